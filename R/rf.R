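# Ontotype + random-forest baseline. No decision-tree package ships with the
# target environment, so a compact random forest is implemented here: bagged
# CART trees with Gini splits and per-node feature subsampling. Pair features
# are the elementwise sum of the two endpoint ontotype rows.

# Best Gini split of y by feature vector x; returns NULL if no valid split.
best_split_feature <- function(x, y, min_leaf) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(ys)
  cut_at <- which(xs[-n] < xs[-1])            # boundaries between distinct values
  cut_at <- cut_at[cut_at >= min_leaf & cut_at <= n - min_leaf]
  if (length(cut_at) == 0L) return(NULL)
  cp <- cumsum(ys)
  pos_tot <- cp[[n]]
  nl <- cut_at; nr <- n - nl
  pl <- cp[cut_at]; pr <- pos_tot - pl
  gini_l <- 1 - (pl / nl)^2 - (1 - pl / nl)^2
  gini_r <- 1 - (pr / nr)^2 - (1 - pr / nr)^2
  impurity <- (nl * gini_l + nr * gini_r) / n
  k <- which.min(impurity)
  list(threshold = (xs[cut_at[k]] + xs[cut_at[k] + 1L]) / 2,
       impurity = impurity[[k]])
}

grow_tree <- function(X, y, mtry, max_depth, min_leaf) {
  nodes <- list()
  new_node <- function(node) {
    nodes[[length(nodes) + 1L]] <<- node
    length(nodes)
  }
  build <- function(rows, depth) {
    yr <- y[rows]
    prob <- mean(yr)
    if (depth >= max_depth || length(rows) < 2L * min_leaf ||
        prob == 0 || prob == 1)
      return(new_node(list(leaf = TRUE, prob = prob)))
    feats <- sample.int(ncol(X), min(mtry, ncol(X)))
    best <- NULL
    parent_gini <- 1 - prob^2 - (1 - prob)^2
    for (fjt in feats) {
      sp <- best_split_feature(X[rows, fjt], yr, min_leaf)
      if (!is.null(sp) && sp$impurity < (best$impurity %||% parent_gini) - 1e-12)
        best <- list(feature = fjt, threshold = sp$threshold,
                     impurity = sp$impurity)
    }
    if (is.null(best))
      return(new_node(list(leaf = TRUE, prob = prob)))
    left_rows <- rows[X[rows, best$feature] <= best$threshold]
    right_rows <- setdiff(rows, left_rows)
    id <- new_node(list(leaf = FALSE, feature = best$feature,
                        threshold = best$threshold, left = NA, right = NA,
                        prob = prob))
    nodes[[id]]$left <<- build(left_rows, depth + 1L)
    nodes[[id]]$right <<- build(right_rows, depth + 1L)
    id
  }
  root <- build(seq_len(nrow(X)), 0L)
  list(nodes = nodes, root = root)
}

predict_tree <- function(tree, X) {
  n <- nrow(X)
  out <- numeric(n)
  at <- rep.int(tree$root, n)
  repeat {
    leaf <- vapply(tree$nodes[at], `[[`, TRUE, "leaf")
    if (all(leaf)) break
    idx <- which(!leaf)
    ids <- at[idx]
    for (id in unique(ids)) {
      node <- tree$nodes[[id]]
      rows <- idx[ids == id]
      go_left <- X[rows, node$feature] <= node$threshold
      at[rows[go_left]] <- node$left
      at[rows[!go_left]] <- node$right
    }
  }
  vapply(tree$nodes[at], `[[`, 0, "prob")
}

#' Fit a random-forest classifier
#'
#' Bagged CART trees: each tree is grown on a bootstrap sample of the rows
#' with `mtry` features considered at every node and Gini impurity as the
#' split criterion. Predictions average the per-tree leaf class fractions.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y 0/1 (or logical) labels.
#' @param n_trees number of trees.
#' @param mtry features sampled per node; default `floor(sqrt(ncol(X)))`.
#' @param max_depth maximum tree depth.
#' @param min_leaf minimum samples per leaf.
#' @param seed integer seed.
#' @return a `random_forest` object for [predict_forest()].
#' @export
fit_random_forest <- function(X, y, n_trees = 25, mtry = NULL,
                              max_depth = 8, min_leaf = 3, seed = 1) {
  X <- as.matrix(X)
  y <- as.integer(as.logical(y))
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(X))))
  trees <- withr::with_seed(seed, lapply(seq_len(n_trees), function(t) {
    rows <- sample.int(nrow(X), replace = TRUE)
    grow_tree(X[rows, , drop = FALSE], y[rows], mtry, max_depth, min_leaf)
  }))
  structure(list(trees = trees, n_features = ncol(X)),
            class = "random_forest")
}

#' Predict class probabilities with a random forest
#'
#' @param forest a [fit_random_forest()] object.
#' @param X feature matrix with the training feature dimension.
#' @return numeric vector of positive-class probabilities.
#' @export
predict_forest <- function(forest, X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == forest$n_features)
  rowMeans(vapply(forest$trees, function(tree) predict_tree(tree, X),
                  numeric(nrow(X))))
}

pair_feature_rows <- function(X, pairs, target_type) {
  schema <- edge_schema(target_type)
  src <- ns_id(as.character(pairs$source), schema[[1L]])
  tgt <- ns_id(as.character(pairs$target), schema[[2L]])
  as.matrix(X[src, , drop = FALSE] + X[tgt, , drop = FALSE])
}

#' Ontotype + random-forest baseline on a shared split plan
#'
#' The non-graph benchmark: each candidate pair is represented by the
#' elementwise sum of its two endpoint ontotype rows (the gene-pair extension
#' of the cell-line/drug feature-sum rule) and fed to a random forest trained
#' per fold on exactly the same splits as the VGAE, with the same metrics and
#' aggregation.
#'
#' @param X feature matrix with namespaced node ids as rownames.
#' @param plan a [make_folds()] plan.
#' @param target_type edge type of the pairs.
#' @param folds fold indices to run.
#' @param n_trees,max_depth,mtry forest hyperparameters
#'   (see [fit_random_forest()]).
#' @param seed integer seed, offset per fold.
#' @param tag optional report label.
#' @return an `eval_report` comparable fold-by-fold with [cross_validate()].
#' @export
rf_baseline <- function(X, plan, target_type, folds = seq_len(plan$k),
                        n_trees = 25, max_depth = 8, mtry = NULL, seed = 1,
                        tag = "ontotype_rf") {
  stopifnot(inherits(plan, "split_plan"))
  rows <- lapply(folds, function(f) {
    fold <- plan$folds[[f]]
    train <- rbind(fold$train, fold$val)
    Xtr <- pair_feature_rows(X, train, target_type)
    forest <- fit_random_forest(Xtr, train$label == "positive",
                                n_trees = n_trees, max_depth = max_depth,
                                mtry = mtry, seed = seed + f)
    scores <- predict_forest(forest, pair_feature_rows(X, fold$test, target_type))
    y <- as.integer(fold$test$label == "positive")
    data.frame(fold = f, auroc = auroc(scores, y), auprc = auprc(scores, y),
               best_epoch = NA_integer_, n_test = nrow(fold$test))
  })
  new_eval_report(do.call(rbind, rows), plan$design, target_type,
                  plan$seed, tag)
}
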