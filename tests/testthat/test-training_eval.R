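# Fold construction, balanced negatives, metrics, cross-validation and the
# sparsity stratification.

pair_df <- function(n, prefix = "p") {
  data.frame(source = sprintf("%s%03d", prefix, seq_len(n)),
             target = sprintf("q%03d", seq_len(n)))
}

test_that("edge_cv folds partition positives with a 90/10 train/val split", {
  plan <- make_folds(pair_df(10), pair_df(40, "n"), k = 5, seed = 1)
  test_pos <- lapply(plan$folds, function(f)
    f$test[f$test$label == "positive", c("source", "target")])
  expect_equal(vapply(test_pos, nrow, 0L), rep(2L, 5))
  combined <- do.call(rbind, test_pos)
  expect_equal(nrow(unique(combined)), 10L)  # folds partition the positives
  f1 <- plan$folds[[1]]
  expect_equal(nrow(f1$val[f1$val$label == "positive", ]), 1L)  # 10% of 8
  plan2 <- make_folds(pair_df(10), pair_df(40, "n"), k = 5, seed = 1)
  expect_identical(plan, plan2)
  expect_error(make_folds(pair_df(3), pair_df(3, "n"), k = 5), "fewer")
})

test_that("cell-line-disjoint folds isolate each cell line in one role", {
  pos <- data.frame(source = rep(sprintf("cl%d", 1:5), each = 4),
                    target = sprintf("g%02d", 1:20))
  neg <- data.frame(source = rep(sprintf("cl%d", 1:5), each = 2),
                    target = sprintf("h%02d", 1:10))
  plan <- make_folds(pos, neg, k = 5, seed = 3,
                     design = "cell_line_disjoint_cv",
                     target_type = "dependency")
  for (f in plan$folds) {
    roles <- lapply(f, function(d) unique(d$source))
    expect_length(roles$test, 1L)   # one cell line per test fold
    expect_length(intersect(roles$train, roles$val), 0L)
    expect_length(intersect(roles$train, roles$test), 0L)
    expect_length(intersect(roles$val, roles$test), 0L)
  }
  test_cells <- vapply(plan$folds, function(f) unique(f$test$source), "")
  expect_setequal(test_cells, sprintf("cl%d", 1:5))
})

test_that("balanced_negatives samples the positive count without replacement", {
  pos <- pair_df(5)
  pool <- pair_df(100, "n")
  s <- balanced_negatives(pos, pool, seed = 2)
  expect_equal(nrow(s), 5L)
  expect_equal(nrow(unique(s)), 5L)
  expect_identical(balanced_negatives(pos, pool, seed = 2), s)
  expect_identical(balanced_negatives(pos, pair_df(5, "n"), seed = 2),
                   pair_df(5, "n"))
  expect_warning(balanced_negatives(pos, pair_df(3, "n")), "fewer")
})

test_that("auroc matches closed forms and the exhaustive concordance oracle", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
  withr::with_seed(31, {
    for (i in 1:50) {
      n <- sample(4:8, 1)
      labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
      scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # force ties
      expect_equal(auroc(scores, labels), brute_auroc(scores, labels))
    }
  })
})

test_that("auprc follows the step-wise summation and its closed forms", {
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  for (m in c(3, 7)) {  # single positive ranked last among m + 1
    scores <- seq(1, 0, length.out = m + 1)
    labels <- c(rep(0, m), 1)
    expect_equal(auprc(scores, labels), 1 / (m + 1))
  }
  expect_error(auprc(1:3, c(0, 0, 0)), "positive")
  # random scores on balanced labels give roughly the prevalence
  withr::with_seed(13, {
    vals <- replicate(100, auprc(runif(40), rep(c(1, 0), 20)))
    expect_lt(abs(mean(vals) - 0.5), 0.05)
  })
})

test_that("cross_validate reports per-fold metrics whose mean it aggregates", {
  cfg <- small_config()
  res <- run_benchmark(cfg, "G", model_config = fast_vgae(), k = 2)
  rep <- res$report
  expect_equal(nrow(rep$folds), 2L)
  expect_equal(rep$mean_auroc, mean(rep$folds$auroc))
  expect_equal(rep$mean_auprc, mean(rep$folds$auprc))
  expect_true(all(rep$folds$auroc >= 0 & rep$folds$auroc <= 1))
  # the small planted world is recoverable even by the fast configuration
  expect_gt(rep$mean_auroc, 0.7)
})

test_that("the masked-edge protocol raises on engineered leakage", {
  cfg <- small_config()
  b <- make_benchmark(cfg)
  g <- benchmark_graph(b, "G")
  pos <- b$gi[b$gi$label == "positive", c("source", "target")]
  negs <- balanced_negatives(pos, b$gi[b$gi$label == "neutral",
                                       c("source", "target")], seed = 1)
  plan <- make_folds(pos, negs, k = 2, seed = 1)
  # masking a different fold's pairs leaves fold-1 positives in the adjacency
  masked_wrong <- mask_target_edges(g, "gi", plan$folds[[2]]$test)
  expect_error(ontolink:::assert_no_leakage(masked_wrong, plan$folds[[1]]),
               "leakage")
})

test_that("the RF baseline is at chance on constant features and above on signal", {
  plan <- make_folds(pair_df(20), pair_df(20, "n"), k = 2, seed = 5)
  ids <- unique(c(outer(c("p", "q", "n"), sprintf("%03d", 1:20), paste0)))
  Xconst <- matrix(1, length(ids), 4, dimnames = list(paste0("gene:", ids), NULL))
  rep_const <- rf_baseline(Xconst, plan, "gi", seed = 7)
  expect_lt(abs(rep_const$mean_auroc - 0.5), 0.15)

  cfg <- small_config()
  res <- run_benchmark(cfg, "G", model_config = fast_vgae(epochs = 2),
                       k = 2, baseline = TRUE)
  expect_gt(res$baseline_report$mean_auroc, 0.6)
})

test_that("sparsity stratification splits at the median and partitions", {
  pairs <- data.frame(source = c("a", "b", "c", "d"),
                      target = c("b", "c", "d", "a"))
  X <- rbind(c(1, 1, 1, 1, 1, 1, 1, 1, 1, 0),
             c(1, 1, 1, 1, 1, 1, 1, 0, 0, 0),
             c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0),
             c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  rownames(X) <- paste0("gene:", c("a", "b", "c", "d"))
  st <- stratify_by_sparsity(pairs, X, "gi")
  # zeros of the summed rows: (a,b) 1/10, (b,c) 3/10, (c,d) 8/10, (d,a) 1/10
  expect_equal(st$sparsity, c(0.1, 0.3, 0.8, 0.1))
  expect_equal(nrow(st$low) + nrow(st$high), 4L)
  expect_setequal(st$low$source, c("a", "d"))   # at or below the median 0.2
  expect_setequal(st$high$source, c("b", "c"))

  Xeq <- matrix(1, 4, 2, dimnames = list(rownames(X), NULL))
  expect_warning(st2 <- stratify_by_sparsity(pairs, Xeq, "gi"), "single")
  expect_equal(nrow(st2$low), 4L)
})
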