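# Variational graph auto-encoder: a learned input-normalization layer
# (Xbar = X W0 + b), a two-layer GCN trunk shared by mean and log-variance
# heads, reparameterized sampling, and an inner-product decoder.
#
#   Xbar   = X W0 + b
#   T      = sigma1( Ahat Xbar W1 )
#   mu     = sigma2( Ahat T W2 );   log sigma^2 = sigma2( Ahat T W3 )
#   Z      = mu + exp(logvar/2) * eps,  eps ~ N(0, 1)
#   Atilde = sigmoid( Z Z^T )
#
# Loss = weighted binary cross-entropy(A, Atilde) + kl_weight * KL(q || N(0,I)).

act_fun <- function(name) {
  switch(name,
         relu = function(x) pmax(x, 0),
         identity = function(x) x,
         sigmoid = sigmoid,
         tanh = tanh,
         stop_ol("unknown activation: ", name))
}

glorot <- function(n_in, n_out) {
  r <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -r, r), n_in, n_out)
}

#' Initialize VGAE parameters
#'
#' Weights use Glorot-uniform initialization; the normalization-layer bias
#' starts at zero.
#'
#' @param f_in input feature dimension (number of retained GO terms).
#' @param h0 width of the learned input-normalization layer.
#' @param h1 width of the GCN trunk layer.
#' @param f embedding dimension of the latent posteriors.
#' @param seed integer seed for the initialization draw.
#' @param sigma1,sigma2 activation names for the trunk and the heads
#'   (`"relu"`, `"identity"`, `"sigmoid"`, `"tanh"`).
#' @param dropout dropout rate applied to each GCN layer input in \[0, 1).
#' @return a `vgae_params` list with `W0`, `b`, `W1`, `W2`, `W3` and the
#'   activation/dropout settings.
#' @export
vgae_params <- function(f_in, h0 = 64, h1 = 32, f = 16, seed = 1,
                        sigma1 = "relu", sigma2 = "identity", dropout = 0) {
  if (dropout < 0 || dropout >= 1) stop_ol("dropout rate must be in [0, 1)")
  withr::with_seed(seed, {
    structure(list(W0 = glorot(f_in, h0), b = numeric(h0),
                   W1 = glorot(h0, h1), W2 = glorot(h1, f), W3 = glorot(h1, f),
                   sigma1 = sigma1, sigma2 = sigma2, dropout = dropout),
              class = "vgae_params")
  })
}

#' Learned input-normalization layer
#'
#' The affine map \eqn{\bar X = X W_0 + b} (bias broadcast across rows). No
#' batch statistics are involved; the map is learned end to end and shares
#' one feature space across gene, cell-line and drug rows.
#'
#' @param X node feature matrix (dense or sparse), n x f_in.
#' @param W0 weight matrix f_in x h0.
#' @param b bias vector of length h0.
#' @return dense n x h0 matrix.
#' @export
input_normalize <- function(X, W0, b) {
  if (ncol(X) != nrow(W0))
    stop_ol("feature dimension ", ncol(X), " does not match W0 rows ", nrow(W0))
  if (length(b) != ncol(W0))
    stop_ol("bias length ", length(b), " does not match W0 columns ", ncol(W0))
  out <- as.matrix(X %*% W0)
  sweep(out, 2L, b, "+")
}

#' One graph-convolution layer
#'
#' Computes `activation(Ahat %*% dropout(H) %*% W)`. Dropout is applied to
#' the layer input, only when `training = TRUE`, with surviving entries
#' scaled by 1/(1 - rate) (inverted dropout).
#'
#' @param Ahat normalized adjacency from [normalize_adjacency()].
#' @param H layer input, n x d.
#' @param W weight matrix d x d'.
#' @param activation activation name (see [vgae_params()]).
#' @param dropout_rate dropout rate in \[0, 1).
#' @param training logical; dropout is active only when `TRUE`.
#' @return dense n x d' matrix.
#' @export
gcn_layer <- function(Ahat, H, W, activation = "identity",
                      dropout_rate = 0, training = FALSE) {
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_ol("dropout rate must be in [0, 1)")
  H <- as.matrix(H)
  if (training && dropout_rate > 0) {
    mask <- matrix(rbinom(length(H), 1L, 1 - dropout_rate), nrow(H), ncol(H))
    H <- H * mask / (1 - dropout_rate)
  }
  act_fun(activation)(as.matrix(Ahat %*% H %*% W))
}

#' Encode node features into latent Gaussian posteriors
#'
#' The trunk \eqn{T = \sigma_1(\hat A \bar X W_1)} is computed once and
#' shared by the two heads \eqn{\mu = \sigma_2(\hat A T W_2)} and
#' \eqn{\log\sigma^2 = \sigma_2(\hat A T W_3)}.
#'
#' @param Ahat normalized adjacency.
#' @param X raw feature matrix (the normalization layer is applied inside).
#' @param params a [vgae_params()] list.
#' @return list with matrices `mu` and `logvar`, both n x f.
#' @export
encode <- function(Ahat, X, params) {
  Xbar <- input_normalize(X, params$W0, params$b)
  Tt <- gcn_layer(Ahat, Xbar, params$W1, params$sigma1)
  list(mu = gcn_layer(Ahat, Tt, params$W2, params$sigma2),
       logvar = gcn_layer(Ahat, Tt, params$W3, params$sigma2))
}

#' Reparameterized sampling of the latent embedding
#'
#' \eqn{Z = \mu + \exp(\mathrm{logvar}/2) \odot \epsilon} with
#' \eqn{\epsilon \sim N(0,1)}. Supplying `eps = 0` (or a zero matrix) gives
#' the deterministic mode `Z = mu`.
#'
#' @param mu,logvar posterior mean and log-variance matrices.
#' @param eps optional noise matrix (recycled scalar allowed); drawn from
#'   `seed` when `NULL`.
#' @param seed integer seed used when `eps` is `NULL`.
#' @return matrix Z of the same shape as `mu`.
#' @export
sample_latent <- function(mu, logvar, eps = NULL, seed = NULL) {
  stopifnot(all(dim(mu) == dim(logvar)))
  if (is.null(eps)) {
    eps <- if (is.null(seed)) matrix(rnorm(length(mu)), nrow(mu), ncol(mu))
           else withr::with_seed(seed, matrix(rnorm(length(mu)), nrow(mu), ncol(mu)))
  }
  if (length(eps) == 1L) eps <- matrix(eps, nrow(mu), ncol(mu))
  mu + exp(logvar / 2) * eps
}

#' Inner-product decoder
#'
#' Reconstructs the adjacency as \eqn{\tilde A = \mathrm{sigmoid}(Z Z^T)}:
#' always symmetric with entries in (0, 1).
#'
#' @param Z latent embedding, n x f.
#' @return dense n x n matrix of link probabilities.
#' @export
decode <- function(Z) {
  sigmoid(decode_logits(Z))
}

#' Decoder logits \eqn{Z Z^T}
#' @inheritParams decode
#' @return dense n x n matrix of pre-sigmoid scores.
#' @export
decode_logits <- function(Z) {
  Z <- as.matrix(Z)
  tcrossprod(Z)
}

#' Weighted binary cross-entropy reconstruction loss
#'
#' Mean over all adjacency entries of the BCE between the target adjacency
#' and `sigmoid(logits)`, with positive entries weighted by `pos_weight`
#' (conventionally the zero/one ratio of the training adjacency, so sparse
#' graphs do not collapse to the all-zero prediction). Computed in the
#' numerically stable logit form, never via `log(0)`.
#'
#' @param A_target binary target adjacency (dense or sparse).
#' @param logits decoder logits of the same shape.
#' @param pos_weight non-negative weight multiplying positive-entry terms.
#' @param weight_mask optional 0/1 matrix; entries with 0 are excluded and
#'   the mean is taken over the included entries.
#' @return scalar loss.
#' @export
reconstruction_loss <- function(A_target, logits, pos_weight = 1,
                                weight_mask = NULL) {
  y <- as.matrix(A_target)
  x <- as.matrix(logits)
  stopifnot(all(dim(y) == dim(x)), pos_weight >= 0)
  ll <- pos_weight * y * softplus(-x) + (1 - y) * softplus(x)
  if (is.null(weight_mask)) mean(ll) else sum(ll * weight_mask) / sum(weight_mask)
}

#' KL divergence of the latent posteriors from the standard normal prior
#'
#' For diagonal Gaussians,
#' \eqn{KL = -\frac{1}{2n}\sum_{i,j}(1 + \mathrm{logvar} - \mu^2 -
#' e^{\mathrm{logvar}})}, i.e. the per-node mean of the usual closed form.
#' Always non-negative.
#'
#' @param mu,logvar posterior mean and log-variance matrices.
#' @return scalar KL value.
#' @export
kl_divergence <- function(mu, logvar) {
  stopifnot(all(dim(mu) == dim(logvar)))
  n <- nrow(mu)
  -0.5 / n * sum(1 + logvar - mu^2 - exp(logvar))
}

#' Composite VGAE loss
#'
#' `total = reconstruction + kl_weight * kl`. The default KL weight is 1/n,
#' the standard VGAE recipe.
#'
#' @inheritParams reconstruction_loss
#' @inheritParams kl_divergence
#' @param kl_weight weight of the KL term; `NULL` means 1/n.
#' @return a `loss_breakdown` list with `reconstruction`, `kl`, `kl_weight`
#'   and `total`.
#' @export
total_loss <- function(A_target, logits, mu, logvar, kl_weight = NULL,
                       pos_weight = 1, weight_mask = NULL) {
  if (is.null(kl_weight)) kl_weight <- 1 / nrow(mu)
  recon <- reconstruction_loss(A_target, logits, pos_weight, weight_mask)
  kl <- kl_divergence(mu, logvar)
  structure(list(reconstruction = recon, kl = kl, kl_weight = kl_weight,
                 total = recon + kl_weight * kl),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss: total=%.6f (reconstruction=%.6f, kl=%.6f, kl_weight=%.4g)\n",
              x$total, x$reconstruction, x$kl, x$kl_weight))
  invisible(x)
}
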