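# Training: full-batch gradient descent on the composite loss with
# hand-derived backpropagation and an adaptive-moment (Adam) optimizer.

#' Training configuration for the VGAE
#'
#' Defaults follow the standard VGAE recipe: hidden widths 64/32, embedding
#' dimension 16, no dropout, learning rate 0.01, up to 200 epochs with early
#' stopping after 20 epochs without validation-AUROC improvement, KL weight
#' 1/n and BCE positive weight equal to the zero/one ratio of the training
#' adjacency.
#'
#' @param h0,h1,f layer widths and embedding dimension.
#' @param dropout dropout rate on GCN layer inputs, in \[0, 1).
#' @param learning_rate Adam step size.
#' @param epochs maximum number of epochs.
#' @param patience early-stopping patience, in epochs.
#' @param min_epochs burn-in: epochs trained before the best-epoch snapshot
#'   and the early-stopping clock become active (capped at `epochs`). With
#'   small validation sets the epoch-wise argmax of validation AUROC is an
#'   overfit estimator, and an initialization-noise spike in the first few
#'   epochs can otherwise be selected over the converged model; the target
#'   edge type can also occupy so small a fraction of the adjacency that its
#'   reconstruction only improves after a transient plateau, which a bare
#'   patience rule mistakes for convergence.
#' @param kl_weight KL term weight; `NULL` means 1/n.
#' @param pos_weight BCE positive weight; `NULL` means (#zeros)/(#ones).
#' @param sigma1 trunk activation (`"relu"` or `"identity"`).
#' @param exclude_masked if `TRUE`, adjacency entries of masked held-out
#'   positive pairs are excluded from the reconstruction loss; by default the
#'   loss covers the full adjacency including the zeroed entries.
#' @param seed integer seed covering initialization and per-epoch noise.
#' @return a `vgae_config` list.
#' @export
vgae_config <- function(h0 = 64, h1 = 32, f = 16, dropout = 0,
                        learning_rate = 0.01, epochs = 200, patience = 20,
                        min_epochs = 100, kl_weight = NULL, pos_weight = NULL,
                        sigma1 = "relu", exclude_masked = FALSE, seed = 1) {
  structure(list(h0 = h0, h1 = h1, f = f, dropout = dropout,
                 learning_rate = learning_rate, epochs = epochs,
                 patience = patience, min_epochs = min_epochs,
                 kl_weight = kl_weight,
                 pos_weight = pos_weight, sigma1 = sigma1,
                 exclude_masked = exclude_masked, seed = seed),
            class = "vgae_config")
}

#' Full forward pass of the VGAE with loss evaluation
#'
#' Runs encoder, sampling, decoder and the composite loss in one call and
#' returns the intermediate quantities needed for backpropagation. The heads
#' use the identity activation (keeping the log-variance unconstrained).
#'
#' @param params a [vgae_params()] list (heads must be `"identity"`).
#' @param Ahat normalized adjacency.
#' @param X feature matrix.
#' @param A_target training adjacency reconstructed by the loss.
#' @param eps noise matrix for [sample_latent()]; `0` gives deterministic
#'   `Z = mu`.
#' @param pos_weight,kl_weight loss weights (see [total_loss()]).
#' @param weight_mask optional 0/1 loss mask.
#' @param training logical; activates dropout.
#' @return list with `loss` (a `loss_breakdown`), `mu`, `logvar`, `Z` and a
#'   `cache` for [vgae_gradients()].
#' @export
vgae_forward <- function(params, Ahat, X, A_target, eps = 0,
                         pos_weight = 1, kl_weight = NULL,
                         weight_mask = NULL, training = FALSE) {
  if (params$sigma2 != "identity")
    stop_ol("analytic training path supports identity heads only")
  n <- nrow(X)
  rate <- params$dropout
  use_drop <- training && rate > 0

  Xbar <- input_normalize(X, params$W0, params$b)
  M1 <- NULL
  D1 <- Xbar
  if (use_drop) {
    M1 <- matrix(rbinom(length(Xbar), 1L, 1 - rate), n, ncol(Xbar)) / (1 - rate)
    D1 <- Xbar * M1
  }
  AX <- as.matrix(Ahat %*% D1)
  S <- AX %*% params$W1
  Tt <- if (params$sigma1 == "relu") pmax(S, 0)
        else if (params$sigma1 == "identity") S
        else stop_ol("analytic training path supports relu/identity trunk only")
  M2 <- NULL
  D2 <- Tt
  if (use_drop) {
    M2 <- matrix(rbinom(length(Tt), 1L, 1 - rate), n, ncol(Tt)) / (1 - rate)
    D2 <- Tt * M2
  }
  AT <- as.matrix(Ahat %*% D2)
  mu <- AT %*% params$W2
  logvar <- AT %*% params$W3
  if (length(eps) == 1L) eps <- matrix(eps, n, ncol(mu))
  Z <- mu + exp(logvar / 2) * eps
  logits <- tcrossprod(Z)

  loss <- total_loss(A_target, logits, mu, logvar, kl_weight, pos_weight,
                     weight_mask)
  list(loss = loss, mu = mu, logvar = logvar, Z = Z,
       cache = list(params = params, Ahat = Ahat, X = X,
                    A_target = as.matrix(A_target), eps = eps,
                    pos_weight = pos_weight, kl_weight = loss$kl_weight,
                    weight_mask = weight_mask,
                    Xbar = Xbar, M1 = M1, AX = AX, S = S, Tt = Tt, M2 = M2,
                    AT = AT, mu = mu, logvar = logvar, Z = Z, logits = logits))
}

#' Analytic gradients of the composite VGAE loss
#'
#' Backpropagates through decoder, reparameterized sampling (noise treated as
#' a constant), both GCN layers and the normalization layer. Verified against
#' central finite differences in the test suite.
#'
#' @param cache the `cache` element returned by [vgae_forward()].
#' @return list of gradients `W0`, `b`, `W1`, `W2`, `W3`.
#' @export
vgae_gradients <- function(cache) {
  with(cache, {
    n <- nrow(mu)
    y <- A_target
    x <- logits
    # d(mean BCE)/d(logits)
    G <- (1 - y) * sigmoid(x) - pos_weight * y * sigmoid(-x)
    if (is.null(weight_mask)) G <- G / length(y)
    else G <- G * weight_mask / sum(weight_mask)

    dZ <- (G + t(G)) %*% Z
    dmu <- dZ + kl_weight * mu / n
    dlogvar <- dZ * (0.5 * exp(logvar / 2) * eps) +
      kl_weight * (0.5 / n) * (exp(logvar) - 1)

    dW2 <- crossprod(AT, dmu)
    dW3 <- crossprod(AT, dlogvar)
    dAT <- tcrossprod(dmu, params$W2) + tcrossprod(dlogvar, params$W3)
    dD2 <- as.matrix(Ahat %*% dAT)          # Ahat symmetric
    dT <- if (is.null(M2)) dD2 else dD2 * M2
    dS <- if (params$sigma1 == "relu") dT * (S > 0) else dT
    dW1 <- crossprod(AX, dS)
    dAX <- tcrossprod(dS, params$W1)
    dD1 <- as.matrix(Ahat %*% dAX)
    dXbar <- if (is.null(M1)) dD1 else dD1 * M1
    dW0 <- as.matrix(Matrix::crossprod(X, dXbar))
    db <- colSums(dXbar)
    list(W0 = dW0, b = db, W1 = dW1, W2 = dW2, W3 = dW3)
  })
}

adam_init <- function(params) {
  nm <- c("W0", "b", "W1", "W2", "W3")
  list(m = lapply(params[nm], function(p) p * 0),
       v = lapply(params[nm], function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

ns_pairs <- function(pairs, target_type) {
  schema <- edge_schema(target_type)
  data.frame(source = ns_id(as.character(pairs$source), schema[[1L]]),
             target = ns_id(as.character(pairs$target), schema[[2L]]),
             label = as.character(pairs$label), stringsAsFactors = FALSE)
}

score_mu_pairs <- function(mu, node_ids, src, tgt) {
  i <- match(src, node_ids); j <- match(tgt, node_ids)
  if (anyNA(i) || anyNA(j))
    stop_ol("pair references node(s) absent from the trained graph")
  unname(sigmoid(rowSums(mu[i, , drop = FALSE] * mu[j, , drop = FALSE])))
}

#' Train the VGAE on a masked heterogeneous graph
#'
#' Full-batch optimization of the composite loss on the training adjacency
#' (one reparameterized noise draw per epoch). After every epoch the AUROC on
#' the validation pairs is computed from the posterior means; the returned
#' model is the snapshot from the best-validation epoch, and training stops
#' early once the validation AUROC has not improved for `patience` epochs.
#' The entire run (initialization, noise, dropout) is reproducible from
#' `config$seed`.
#'
#' @param masked a [mask_target_edges()] result; held-out positives are
#'   absent from the training adjacency.
#' @param X feature matrix aligned to the graph node order.
#' @param val_pairs data.frame of validation pairs (`source`, `target` raw
#'   ids in the target-type schema order, `label`) used for model selection
#'   and early stopping.
#' @param config a [vgae_config()].
#' @return a `vgae_model`: list with `params` (best epoch), `mu`, `logvar`,
#'   `history` (per-epoch data.frame: loss components and validation AUROC),
#'   `best_epoch`, `node_ids`, `target_type`, `config`.
#' @export
train_vgae <- function(masked, X, val_pairs, config = vgae_config()) {
  stopifnot(inherits(masked, "masked_graph"))
  node_ids <- masked$graph$nodes$id
  stopifnot(nrow(X) == length(node_ids))
  # reconstruction label is the self-loop-augmented training adjacency, the
  # reference VGAE recipe: diag(Z Z^T) >= 0 pins diagonal scores at or above
  # one half, so a zero-diagonal label would put a floor under the loss
  A_target <- as.matrix(masked$train_adjacency) + diag(nrow(masked$train_adjacency))
  n <- nrow(A_target)

  n_pos <- sum(A_target)
  pos_weight <- config$pos_weight %||%
    (if (n_pos > 0) (length(A_target) - n_pos) / n_pos else 1)
  kl_weight <- config$kl_weight %||% (1 / n)
  weight_mask <- NULL
  if (isTRUE(config$exclude_masked)) {
    weight_mask <- matrix(1, n, n, dimnames = dimnames(A_target))
    hp <- masked$heldout[masked$heldout$label == "positive", , drop = FALSE]
    weight_mask[cbind(hp$source, hp$target)] <- 0
    weight_mask[cbind(hp$target, hp$source)] <- 0
  }

  vp <- ns_pairs(val_pairs, masked$target_type)
  val_y <- as.integer(vp$label == "positive")
  if (length(unique(val_y)) < 2L)
    stop_ol("validation pairs must contain both labels")

  Ahat <- normalize_adjacency(masked$train_adjacency)

  withr::with_seed(config$seed, {
    params <- structure(
      list(W0 = glorot(ncol(X), config$h0), b = numeric(config$h0),
           W1 = glorot(config$h0, config$h1),
           W2 = glorot(config$h1, config$f), W3 = glorot(config$h1, config$f),
           sigma1 = config$sigma1, sigma2 = "identity",
           dropout = config$dropout),
      class = "vgae_params")
    state <- adam_init(params)

    history <- data.frame(epoch = integer(), reconstruction = numeric(),
                          kl = numeric(), total = numeric(),
                          val_auroc = numeric())
    best <- list(auroc = -Inf, params = params, mu = NULL, logvar = NULL,
                 epoch = 0L)
    stall <- 0L
    burn_in <- min(config$min_epochs %||% 1L, config$epochs)

    for (epoch in seq_len(config$epochs)) {
      eps <- matrix(rnorm(n * config$f), n, config$f)
      fwd <- vgae_forward(params, Ahat, X, A_target, eps = eps,
                          pos_weight = pos_weight, kl_weight = kl_weight,
                          weight_mask = weight_mask, training = TRUE)
      if (!is.finite(fwd$loss$total))
        stop_ol("non-finite loss at epoch ", epoch,
                " (reconstruction=", fwd$loss$reconstruction,
                ", kl=", fwd$loss$kl, "); try a lower learning rate")
      grads <- vgae_gradients(fwd$cache)
      upd <- adam_step(params, grads, state, config$learning_rate)
      params <- upd$params; state <- upd$state

      # deterministic validation scoring from the posterior means
      post <- encode(Ahat, X, params)
      val_scores <- score_mu_pairs(post$mu, node_ids, vp$source, vp$target)
      val_auroc <- auroc(val_scores, val_y)

      history <- rbind(history, data.frame(
        epoch = epoch, reconstruction = fwd$loss$reconstruction,
        kl = fwd$loss$kl, total = fwd$loss$total, val_auroc = val_auroc))

      if (epoch >= burn_in) {
        if (val_auroc > best$auroc + 1e-12) {
          best <- list(auroc = val_auroc, params = params, mu = post$mu,
                       logvar = post$logvar, epoch = epoch)
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= config$patience) break
        }
      }
    }
  })

  structure(list(params = best$params, mu = best$mu, logvar = best$logvar,
                 history = history, best_epoch = best$epoch,
                 best_val_auroc = best$auroc, node_ids = node_ids,
                 target_type = masked$target_type, config = config,
                 pos_weight = pos_weight, kl_weight = kl_weight),
            class = "vgae_model")
}

#' @export
print.vgae_model <- function(x, ...) {
  cat("vgae_model: ", length(x$node_ids), " nodes, f=", ncol(x$mu),
      "; best epoch ", x$best_epoch, " (val AUROC ",
      sprintf("%.3f", x$best_val_auroc), ") of ", nrow(x$history),
      " run\n", sep = "")
  invisible(x)
}

#' Score candidate links with a trained model
#'
#' Deterministic inference from the posterior means:
#' `score(i, j) = sigmoid(mu_i . mu_j)`, identical to the corresponding
#' entries of `decode(mu)`.
#'
#' @param model a [train_vgae()] result.
#' @param pairs data.frame with `source`, `target` raw ids in the schema
#'   order of `target_type`.
#' @param target_type edge type of the pairs; defaults to the model's own.
#' @return numeric vector of link probabilities.
#' @export
predict_links <- function(model, pairs, target_type = model$target_type) {
  stopifnot(inherits(model, "vgae_model"))
  schema <- edge_schema(target_type)
  src <- ns_id(as.character(pairs$source), schema[[1L]])
  tgt <- ns_id(as.character(pairs$target), schema[[2L]])
  score_mu_pairs(model$mu, model$node_ids, src, tgt)
}

#' Save a trained model as a flat text checkpoint
#'
#' Writes each parameter array as TSV plus a JSON config, and the training
#' history as TSV, under `dir`.
#'
#' @param model a `vgae_model`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_checkpoint <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("W0", "W1", "W2", "W3"))
    write.table(model$params[[nm]], file.path(dir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(data.frame(b = model$params$b), file.path(dir, "b.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(sigma1 = model$params$sigma1, sigma2 = model$params$sigma2,
         dropout = model$params$dropout, target_type = model$target_type,
         best_epoch = model$best_epoch, config = unclass(model$config)),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA, null = "null")
  write.table(model$history, file.path(dir, "history.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
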