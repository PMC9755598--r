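# Evaluation protocol: masked-edge cross-validation with balanced negative
# resampling, validation splits for early stopping, AUROC/AUPRC metrics, and
# sparsity-stratified reporting.

#' Build a cross-validation split plan over target pairs
#'
#' `edge_cv` shuffles the positive pairs into `k` near-equal test folds; each
#' fold's complement is further split 90/10 into train and validation pairs.
#' Negatives are assigned to folds by the same rule, independently.
#' `cell_line_disjoint_cv` instead partitions the cell lines into `k` groups
#' and assigns every pair to the fold of its cell line, so that no cell line
#' appears in more than one of train/validation/test of any fold.
#'
#' @param positives,negatives data.frames of pairs (`source`, `target`).
#' @param k number of folds (>= 2).
#' @param seed integer seed; the plan is deterministic given the seed.
#' @param design `"edge_cv"` or `"cell_line_disjoint_cv"`.
#' @param target_type edge type of the pairs; required for the cell-disjoint
#'   design to locate the cell-line side of each pair.
#' @return a `split_plan`: list with `design`, `k`, `seed`, `target_type` and
#'   `folds`, a list of `k` lists each holding `train`, `val`, `test`
#'   data.frames (`source`, `target`, `label`).
#' @export
make_folds <- function(positives, negatives, k = 5, seed = 1,
                       design = c("edge_cv", "cell_line_disjoint_cv"),
                       target_type = NULL) {
  design <- match.arg(design)
  if (k < 2) stop_ol("k must be at least 2")
  if (nrow(positives) < k)
    stop_ol("fewer positive pairs (", nrow(positives), ") than folds (", k, ")")
  positives <- data.frame(source = as.character(positives$source),
                          target = as.character(positives$target),
                          label = "positive", stringsAsFactors = FALSE)
  negatives <- data.frame(source = as.character(negatives$source),
                          target = as.character(negatives$target),
                          label = "neutral", stringsAsFactors = FALSE)

  folds <- withr::with_seed(seed, {
    if (design == "edge_cv") {
      split_edges <- function(df) {
        ord <- sample.int(nrow(df))
        fold_of <- rep_len(seq_len(k), nrow(df))[order(ord)]
        lapply(seq_len(k), function(f) {
          test <- df[fold_of == f, , drop = FALSE]
          rest <- df[fold_of != f, , drop = FALSE]
          n_val <- max(1L, round(0.1 * nrow(rest)))
          vi <- sample.int(nrow(rest), n_val)
          list(test = test, val = rest[vi, , drop = FALSE],
               train = rest[-vi, , drop = FALSE])
        })
      }
      fp <- split_edges(positives)
      fn <- split_edges(negatives)
      lapply(seq_len(k), function(f)
        list(train = rbind(fp[[f]]$train, fn[[f]]$train),
             val = rbind(fp[[f]]$val, fn[[f]]$val),
             test = rbind(fp[[f]]$test, fn[[f]]$test)))
    } else {
      if (is.null(target_type))
        stop_ol("cell_line_disjoint_cv requires target_type")
      side <- which(edge_schema(target_type) == "cell_line")
      if (length(side) != 1L)
        stop_ol("edge type '", target_type, "' has no cell-line side")
      cell_of <- function(df) if (side == 1L) df$source else df$target
      cells <- sort(unique(c(cell_of(positives), cell_of(negatives))))
      if (length(cells) < k)
        stop_ol("fewer cell lines (", length(cells), ") than folds (", k, ")")
      grp <- rep_len(seq_len(k), length(cells))[order(sample.int(length(cells)))]
      names(grp) <- cells
      lapply(seq_len(k), function(f) {
        rest_cells <- cells[grp != f]
        n_val <- max(1L, round(0.1 * length(rest_cells)))
        val_cells <- rest_cells[sample.int(length(rest_cells), n_val)]
        pick <- function(df, wanted) df[cell_of(df) %in% wanted, , drop = FALSE]
        all_pairs <- rbind(positives, negatives)
        list(train = pick(all_pairs, setdiff(rest_cells, val_cells)),
             val = pick(all_pairs, val_cells),
             test = pick(all_pairs, cells[grp == f]))
      })
    }
  })
  folds <- lapply(folds, function(f) lapply(f, function(d) {
    rownames(d) <- NULL
    d
  }))
  structure(list(design = design, k = k, seed = seed,
                 target_type = target_type, folds = folds),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("split_plan: ", x$design, ", k=", x$k, ", seed=", x$seed, "\n", sep = "")
  sizes <- vapply(x$folds, function(f) vapply(f, nrow, 0L), integer(3))
  cat("  pairs per fold (train/val/test):",
      paste(apply(sizes, 2, paste, collapse = "/"), collapse = ", "), "\n")
  invisible(x)
}

#' Sample a balanced set of evaluation negatives
#'
#' Uniform sampling without replacement from the candidate pool, of the same
#' size as the positive set. For the 10-repetition balanced-resampling
#' protocol, repetition r should pass `seed + r`. Sets drawn under different
#' seeds are not guaranteed disjoint.
#'
#' @param positives data.frame of positive pairs (only its row count is used).
#' @param candidate_negatives data.frame of candidate negative pairs.
#' @param seed integer seed.
#' @return a data.frame of sampled negative pairs. If the pool is smaller
#'   than the positive set, the whole pool is returned with a warning.
#' @export
balanced_negatives <- function(positives, candidate_negatives, seed = 1) {
  n <- nrow(positives)
  if (nrow(candidate_negatives) <= n) {
    if (nrow(candidate_negatives) < n)
      warning("candidate negatives (", nrow(candidate_negatives),
              ") fewer than positives (", n, "); using all")
    return(candidate_negatives)
  }
  withr::with_seed(seed, {
    idx <- sample.int(nrow(candidate_negatives), n)
    out <- candidate_negatives[idx, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a uniformly chosen
#' positive outscores a uniformly chosen negative, ties counted one half.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or logical) class labels; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop_ol("AUROC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise summation \eqn{\sum_i (R_i - R_{i-1}) P_i} over descending
#' score thresholds (average precision; no trapezoid interpolation). Tied
#' scores are treated as a single threshold.
#'
#' @inheritParams auroc
#' @return AUPRC in (0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop_ol("AUPRC needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  # last index of each tied-score block
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

new_eval_report <- function(fold_df, design, target_type, seed, tag = NULL) {
  structure(list(folds = fold_df,
                 mean_auroc = mean(fold_df$auroc), sd_auroc = stats::sd(fold_df$auroc),
                 mean_auprc = mean(fold_df$auprc), sd_auprc = stats::sd(fold_df$auprc),
                 design = design, target_type = target_type, seed = seed,
                 tag = tag),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report", if (!is.null(x$tag)) paste0(" [", x$tag, "]"),
      ": ", x$target_type, ", ", x$design, ", ", nrow(x$folds),
      " fold(s)\n", sep = "")
  cat(sprintf("  AUROC %.4f (sd %.4f)   AUPRC %.4f (sd %.4f)\n",
              x$mean_auroc, x$sd_auroc %||% NA, x$mean_auprc, x$sd_auprc %||% NA))
  invisible(x)
}

#' Merge evaluation reports (e.g. balanced-resampling repetitions)
#'
#' @param reports list of `eval_report`s over the same target.
#' @return one `eval_report` whose fold table stacks all inputs; overall
#'   means are the arithmetic means of the stacked fold values.
#' @export
combine_reports <- function(reports) {
  fold_df <- do.call(rbind, lapply(seq_along(reports), function(i) {
    df <- reports[[i]]$folds
    df$repetition <- i
    df
  }))
  new_eval_report(fold_df, reports[[1L]]$design, reports[[1L]]$target_type,
                  reports[[1L]]$seed, reports[[1L]]$tag)
}

#' Write an evaluation report as JSON and TSV
#'
#' @param report an `eval_report`.
#' @param json_path,tsv_path output paths (either may be `NULL`).
#' @return `report`, invisibly.
#' @export
write_eval_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(
      list(design = report$design, target_type = report$target_type,
           seed = report$seed, tag = report$tag,
           mean_auroc = report$mean_auroc, sd_auroc = report$sd_auroc,
           mean_auprc = report$mean_auprc, sd_auprc = report$sd_auprc,
           folds = report$folds),
      json_path, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(tsv_path))
    write.table(report$folds, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(report)
}

# Abort if any held-out (test or validation) positive of the target type is
# still an edge of the training adjacency.
assert_no_leakage <- function(masked, fold) {
  schema <- edge_schema(masked$target_type)
  held <- rbind(fold$test, fold$val)
  held <- held[held$label == "positive", , drop = FALSE]
  if (nrow(held) == 0L) return(invisible(TRUE))
  node_ids <- masked$graph$nodes$id
  i <- match(ns_id(held$source, schema[[1L]]), node_ids)
  j <- match(ns_id(held$target, schema[[2L]]), node_ids)
  if (any(masked$train_adjacency[cbind(i, j)] != 0))
    stop_ol("leakage: held-out positive pair present in training adjacency")
  invisible(TRUE)
}

#' Masked-edge cross-validation of the VGAE
#'
#' For every fold: the fold's test and validation positives are masked out of
#' the adjacency (a leakage assertion verifies this), the model is trained
#' with early stopping on the fold's validation pairs, the test pairs are
#' scored from the posterior means, and AUROC/AUPRC are computed. Fold
#' metrics are averaged unweighted.
#'
#' @param graph a `hetero_graph` containing the target edges.
#' @param X feature matrix aligned to the graph nodes.
#' @param plan a [make_folds()] plan over the target pairs.
#' @param target_type edge type being predicted.
#' @param config a [vgae_config()]; the model seed is offset by the fold
#'   index so folds differ but the whole run is reproducible.
#' @param folds integer vector of fold indices to run (default: all).
#' @param tag optional label stored in the report.
#' @return an `eval_report`.
#' @export
cross_validate <- function(graph, X, plan, target_type,
                           config = vgae_config(), folds = seq_len(plan$k),
                           tag = NULL) {
  stopifnot(inherits(plan, "split_plan"))
  rows <- lapply(folds, function(f) {
    fold <- plan$folds[[f]]
    heldout <- rbind(fold$test, fold$val)
    masked <- mask_target_edges(graph, target_type, heldout)
    assert_no_leakage(masked, fold)
    cfg <- config
    cfg$seed <- config$seed + f
    model <- train_vgae(masked, X, fold$val, cfg)
    scores <- predict_links(model, fold$test)
    y <- as.integer(fold$test$label == "positive")
    data.frame(fold = f, auroc = auroc(scores, y), auprc = auprc(scores, y),
               best_epoch = model$best_epoch, n_test = nrow(fold$test))
  })
  new_eval_report(do.call(rbind, rows), plan$design, target_type,
                  plan$seed, tag)
}

#' Split test pairs into low- and high-sparsity strata
#'
#' Pair sparsity is the fraction of zero entries of the elementwise sum of
#' the two endpoint feature rows. Pairs at or below the median sparsity form
#' the low stratum (for an odd count the low stratum takes the median
#' element); the rest form the high stratum.
#'
#' @param pairs data.frame with `source`, `target` raw ids.
#' @param X feature matrix with namespaced node ids as rownames.
#' @param target_type edge type of the pairs (namespacing).
#' @return list with `low`, `high` (data.frames, union = input) and
#'   `sparsity` (per-pair values). All-equal sparsities give a single stratum
#'   with a warning.
#' @export
stratify_by_sparsity <- function(pairs, X, target_type) {
  schema <- edge_schema(target_type)
  src <- ns_id(as.character(pairs$source), schema[[1L]])
  tgt <- ns_id(as.character(pairs$target), schema[[2L]])
  sp <- vapply(seq_len(nrow(pairs)),
               function(i) pair_sparsity(X, src[[i]], tgt[[i]]), 0)
  if (length(unique(sp)) == 1L) {
    warning("all pair sparsities equal; returning a single stratum")
    return(list(low = pairs, high = pairs[0, , drop = FALSE], sparsity = sp))
  }
  med <- median(sp)
  list(low = pairs[sp <= med, , drop = FALSE],
       high = pairs[sp > med, , drop = FALSE],
       sparsity = sp)
}
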