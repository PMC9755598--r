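# Synthetic benchmark generator: ontology, annotations, planted edges,
# bundle round trips and determinism.

test_that("make_ontology grows a rooted tree that round-trips through OBO", {
  cfg1 <- sim_config(n_terms = 1, terms_per_gene = 1, n_modules = 1,
                     n_genes = 3, seed = 2)
  dag1 <- make_ontology(cfg1)
  expect_length(dag1$terms, 1L)
  expect_equal(dag1$parents[[1]], character())

  cfg <- small_config()
  dag <- make_ontology(cfg)
  expect_equal(sum(lengths(dag$parents)), cfg$n_terms - 1L)  # tree property
  expect_true(all(table(unlist(dag$parents)) <= cfg$dag_branching))
  dag2 <- parse_obo(write_obo(dag))
  expect_equal(dag2$terms, dag$terms)
  expect_equal(dag2$parents, dag$parents)
  expect_equal(dag2$namespace, dag$namespace)
})

test_that("annotations are leaf-biased, module-pooled and evidence-mixed", {
  cfg <- small_config()
  dag <- make_ontology(cfg)
  ann <- make_annotations(dag, cfg)
  expect_length(ann$direct, cfg$n_genes)
  expect_true(all(vapply(ann$direct, nrow, 0L) == cfg$terms_per_gene))
  # roughly 10% IGI rows, binomially
  ev <- unlist(lapply(ann$direct, `[[`, "evidence"))
  n <- length(ev)
  expect_gte(sum(ev == "IGI"), qbinom(1e-4, n, 0.1))
  expect_lte(sum(ev == "IGI"), qbinom(1 - 1e-4, n, 0.1))
  # the IGI filter removes exactly those rows
  kept <- filter_annotations(ann)
  expect_equal(sum(vapply(kept$direct, nrow, 0L)), sum(ev != "IGI"))
  # deterministic under the config seed
  expect_identical(make_annotations(dag, cfg)$direct, ann$direct)

  # degenerate single-module case: every gene annotated everywhere
  cfg_all <- sim_config(n_terms = 5, terms_per_gene = 5, n_modules = 1,
                        n_genes = 4, seed = 1)
  ann_all <- make_annotations(make_ontology(cfg_all), cfg_all)
  expect_true(all(vapply(ann_all$direct, nrow, 0L) == 5L))
})

test_that("plant_edges maps similarity to probability as specified", {
  rows <- rbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0), c = c(0, 0, 1, 1))
  res <- plant_edges(rows, data.frame(source = c("a", "a"),
                                      target = c("b", "c")),
                     alpha = 0.05, beta = 50, seed = 1)
  expect_gt(res$truth$probability[1], 0.99)   # identical supports, large beta
  expect_equal(res$truth$probability[2], 0.05)  # disjoint supports: p = alpha
  expect_equal(res$truth$similarity, c(1, 0))
  expect_error(plant_edges(rows, data.frame(source = "a", target = "b"),
                           alpha = 1.5, beta = 1), "alpha")
})

test_that("beta = 0 plants pure noise at the base rate", {
  withr::with_seed(77, {
    n_items <- 150
    rows <- matrix(rbinom(n_items * 20, 1, 0.3), n_items, 20,
                   dimnames = list(sprintf("i%03d", 1:n_items), NULL))
    pairs <- expand.grid(source = rownames(rows)[1:100],
                         target = rownames(rows)[101:150],
                         stringsAsFactors = FALSE)
  })
  res <- plant_edges(rows, pairs, alpha = 0.02, beta = 0, seed = 3)
  n <- nrow(pairs)
  rate <- mean(res$table$label == "positive")
  expect_lt(abs(rate - 0.02), 3 * sqrt(0.02 * 0.98 / n))
  expect_true(all(res$truth$probability == 0.02))
})

test_that("bundles re-parse through the io readers with zero warnings", {
  cfg <- small_config()
  b <- make_benchmark(cfg)
  dir <- withr::local_tempdir()
  write_benchmark(b, dir)
  expect_no_warning({
    dag <- parse_obo(file.path(dir, "ontology.obo"))
    ann <- parse_annotations(file.path(dir, "annotations.gaf"), dag)
    for (nm in c("gi", "dependency", "mutation", "drug_target", "sensitivity"))
      read_edge_table(file.path(dir, paste0(nm, ".tsv")), nm)
  })
  rb <- read_benchmark(dir)
  expect_equal(rb$dag$parents, b$dag$parents)
  expect_equal(as.data.frame(rb$gi), as.data.frame(b$gi))
  # the reader keeps IGI rows so filtering stays a caller decision
  expect_equal(sum(vapply(rb$annotations$direct, nrow, 0L)),
               sum(vapply(b$annotations$direct, nrow, 0L)))
})

test_that("identical (config, seed) produce byte-identical bundles", {
  cfg <- small_config(seed = 9)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_benchmark(make_benchmark(cfg), d1)
  write_benchmark(make_benchmark(cfg), d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files)
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = f)
  # different seed, different draws
  b3 <- make_benchmark(small_config(seed = 10))
  expect_false(identical(as.data.frame(b3$gi),
                         as.data.frame(make_benchmark(cfg)$gi)))
})

test_that("held-out AUROC is non-decreasing in the signal strength", {
  mean_auc <- function(beta) {
    mean(sapply(1:3, function(s) {
      res <- run_benchmark(small_config(seed = s, signal_strength = beta),
                           "G", model_config = fast_vgae(), k = 5, folds = 1)
      res$report$mean_auroc
    }))
  }
  aucs <- vapply(c(0, 1, 4), mean_auc, 0)
  expect_true(all(diff(aucs) >= -0.02))  # non-decreasing up to fold noise
  expect_gt(aucs[3], aucs[1])
})
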