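# Encoder/decoder algebra, losses, sampling and the training loop.

scalar_params <- function(w0 = 1, b = 0, w1 = 1, w2 = 1, w3 = 2,
                          sigma1 = "identity") {
  structure(list(W0 = matrix(w0), b = b, W1 = matrix(w1), W2 = matrix(w2),
                 W3 = matrix(w3), sigma1 = sigma1, sigma2 = "identity",
                 dropout = 0),
            class = "vgae_params")
}

test_that("input_normalize is the affine map X W0 + b", {
  X <- matrix(rnorm(6), 2, 3)
  expect_equal(input_normalize(X, diag(3), rep(0, 3)), X)
  expect_equal(input_normalize(matrix(0, 2, 3), diag(3), c(1, 2, 3)),
               rbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(input_normalize(matrix(2), matrix(3), 1), matrix(7))
  expect_error(input_normalize(X, diag(2), rep(0, 2)), "dimension")
})

test_that("gcn_layer applies propagation, weights, activation and dropout rules", {
  H <- matrix(rnorm(4), 2, 2)
  expect_equal(gcn_layer(diag(2), H, diag(2)), H)
  expect_equal(gcn_layer(diag(2), -abs(H), diag(2), activation = "relu"),
               matrix(0, 2, 2))
  Ah <- normalize_adjacency(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(gcn_layer(Ah, matrix(c(1, 0), 2, 1), matrix(1)),
               matrix(c(0.5, 0.5), 2, 1))
  expect_error(gcn_layer(diag(2), H, diag(2), dropout_rate = 1), "rate")
  # dropout is inactive outside training and unbiased in expectation
  expect_equal(gcn_layer(diag(2), H, diag(2), dropout_rate = 0.5), H)
})

test_that("encode shares the trunk and matches the scalar chain", {
  p0 <- vgae_params(3, h0 = 2, h1 = 2, f = 2, seed = 1)
  p0$W2[] <- 0; p0$W3[] <- 0
  enc <- encode(diag(4), matrix(rnorm(12), 4, 3), p0)
  expect_equal(enc$mu, matrix(0, 4, 2))
  expect_equal(enc$logvar, matrix(0, 4, 2))

  enc1 <- encode(matrix(1), matrix(1), scalar_params())
  expect_equal(enc1$mu, matrix(1))
  expect_equal(enc1$logvar, matrix(2))
})

test_that("encode equals the loop-based entrywise oracle", {
  withr::with_seed(23, {
    for (i in 1:10) {
      n <- sample(2:4, 1)
      A <- random_adjacency(n)
      Ah <- normalize_adjacency(A)
      X <- matrix(rnorm(n * 3), n, 3)
      p <- vgae_params(3, h0 = 3, h1 = 2, f = 2, seed = i)
      enc <- encode(Ah, X, p)
      oracle <- brute_encode(Ah, X, p)
      expect_equal(enc$mu, oracle$mu, tolerance = 1e-10)
      expect_equal(enc$logvar, oracle$logvar, tolerance = 1e-10)
    }
  })
})

test_that("reparameterized sampling follows Z = mu + exp(logvar/2) * eps", {
  mu <- matrix(rnorm(6), 3, 2)
  lv <- matrix(0, 3, 2)
  expect_equal(sample_latent(mu, lv, eps = 0), mu)
  expect_equal(sample_latent(mu, lv, eps = 1), mu + 1)
  expect_equal(sample_latent(mu, lv, seed = 9), sample_latent(mu, lv, seed = 9))
  lv2 <- matrix(log(4), 3, 2)
  expect_equal(sample_latent(mu, lv2, eps = 1), mu + 2)
})

test_that("decoder is a symmetric sigmoid inner product", {
  expect_equal(decode(matrix(0, 3, 2)), matrix(0.5, 3, 3))
  At <- decode(diag(2))
  expect_equal(At[1, 2], 0.5)
  expect_equal(At[1, 1], 1 / (1 + exp(-1)))
  Z <- matrix(rnorm(12), 4, 3)
  expect_equal(decode(Z), t(decode(Z)))
})

test_that("reconstruction loss has the stated closed forms and is stable", {
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  zero_logits <- matrix(0, 2, 2)
  expect_equal(reconstruction_loss(A, zero_logits, pos_weight = 1), log(2))
  expect_equal(reconstruction_loss(matrix(0, 3, 3), matrix(0, 3, 3)), log(2))
  # perfect +-large logits drive the loss to 0 without producing NaN
  perfect <- ifelse(A == 1, 500, -500)
  expect_true(is.finite(reconstruction_loss(A, perfect)))
  expect_lt(reconstruction_loss(A, perfect), 1e-12)
})

test_that("KL divergence has its closed forms and is non-negative", {
  expect_equal(kl_divergence(matrix(0), matrix(0)), 0)
  expect_equal(kl_divergence(matrix(1), matrix(0)), 0.5)
  withr::with_seed(5, {
    for (i in 1:1000) {
      mu <- matrix(rnorm(4, sd = 2), 2, 2)
      lv <- matrix(rnorm(4, sd = 2), 2, 2)
      expect_gte(kl_divergence(mu, lv), 0)
    }
  })
})

test_that("total loss recombines additively with the KL weight", {
  withr::with_seed(2, {
    A <- random_adjacency(4)
    Z <- matrix(rnorm(8), 4, 2)
    mu <- matrix(rnorm(8), 4, 2); lv <- matrix(rnorm(8), 4, 2)
    L <- total_loss(A, tcrossprod(Z), mu, lv, kl_weight = 0.3, pos_weight = 2)
    expect_equal(L$total - 0.3 * L$kl, L$reconstruction)
    L0 <- total_loss(A, tcrossprod(Z), mu, lv, kl_weight = 0)
    expect_equal(L0$total, L0$reconstruction)
    Ldef <- total_loss(A, tcrossprod(Z), mu, lv)
    expect_equal(Ldef$kl_weight, 1 / 4)
  })
})

test_that("training reduces the loss, memorizes without KL, and is deterministic", {
  gi <- read_edge_table(data.frame(source = c("a", "b", "c"),
                                   target = c("b", "c", "d")), "gi")
  g <- build_gi_graph(gi)
  X <- diag(4); rownames(X) <- g$nodes$id
  masked <- mask_target_edges(g, "gi",
                              data.frame(source = character(),
                                         target = character(),
                                         label = character()))
  val <- data.frame(source = c("a", "a"), target = c("b", "c"),
                    label = c("positive", "neutral"))
  cfg <- vgae_config(h0 = 8, h1 = 8, f = 8, epochs = 250, patience = 250,
                     min_epochs = 1, learning_rate = 0.05,
                     kl_weight = 0, pos_weight = 1, seed = 3)
  m <- train_vgae(masked, X, val, cfg)
  h <- m$history
  expect_lt(h$total[nrow(h)], h$total[1])  # optimizer sanity
  # memorization limit: with no KL pressure a wide model fits a tiny graph
  expect_lt(min(h$reconstruction), 0.1)

  m2 <- train_vgae(masked, X, val, cfg)
  expect_identical(m2$history, m$history)
})

test_that("predict_links equals decode(mu) at the same positions", {
  cfg <- small_config()
  b <- make_benchmark(cfg)
  g <- benchmark_graph(b, "G")
  X <- benchmark_features(b, g)
  pos <- b$gi[b$gi$label == "positive", c("source", "target")]
  neg <- b$gi[b$gi$label == "neutral", c("source", "target")][1:20, ]
  heldout <- rbind(cbind(pos[1:5, ], label = "positive"),
                   cbind(neg[1:5, ], label = "neutral"))
  masked <- mask_target_edges(g, "gi", heldout)
  m <- train_vgae(masked, X, heldout, fast_vgae(epochs = 5))
  sc <- predict_links(m, heldout)
  At <- decode(m$mu)
  idx_i <- match(paste0("gene:", heldout$source), m$node_ids)
  idx_j <- match(paste0("gene:", heldout$target), m$node_ids)
  expect_equal(sc, At[cbind(idx_i, idx_j)])
  expect_error(predict_links(m, data.frame(source = "nope", target = "a")),
               "absent")
})
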