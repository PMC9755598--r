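# Heterogeneous graph assembly, adjacency normalization and target masking.

gi_table <- function(src, tgt, label = "positive") {
  read_edge_table(data.frame(source = src, target = tgt, label = label), "gi")
}

test_that("build_gi_graph uses positive pairs as edges, neutrals as negatives", {
  gi <- gi_table(c("a", "b", "a"), c("b", "c", "c"),
                 c("positive", "positive", "neutral"))
  g <- build_gi_graph(gi)
  expect_equal(nrow(g$nodes), 3L)
  A <- g$adjacency
  expect_equal(A["gene:a", "gene:b"], 1)
  expect_equal(A["gene:b", "gene:c"], 1)
  expect_equal(A["gene:a", "gene:c"], 0)
  expect_equal(nrow(g$neutrals), 1L)
  expect_error(build_gi_graph(gi_table("a", "b", "neutral")), "no positive")
})

test_that("build_cd_graph unions gene universes and tolerates degenerate input", {
  gi <- gi_table("g1", "g2")
  dep <- read_edge_table(data.frame(source = c("cl1", "cl2"),
                                    target = c("g1", "g3"),
                                    label = c("positive", "neutral")),
                         "dependency")
  expect_warning(g <- build_cd_graph(gi, dep), "isolated")
  expect_setequal(g$nodes$id, c("gene:g1", "gene:g2", "gene:g3",
                                "cell:cl1", "cell:cl2"))
  expect_equal(nrow(g$edges), 2L)
  dep_pos <- read_edge_table(data.frame(source = "cl1", target = "g1"),
                             "dependency")
  expect_warning(build_cd_graph(NULL, dep_pos), "bipartite")
})

test_that("build_ds_graph assembles all four edge types with canonical order", {
  gi <- gi_table("g1", "g2")
  mut <- read_edge_table(data.frame(source = "cl1", target = "g1"), "mutation")
  tgt <- read_edge_table(data.frame(source = "d1", target = "g1"), "drug_target")
  sens <- read_edge_table(data.frame(source = c("d1", "d2"),
                                     target = c("cl1", "cl1")), "sensitivity")
  expect_warning(g <- build_ds_graph(gi, mut, tgt, sens), "no\\s+target")
  expect_equal(g$nodes$type, c("gene", "gene", "cell_line", "drug", "drug"))
  expect_equal(nrow(g$edges), 5L)
  # node order independent of input row order
  sens2 <- read_edge_table(data.frame(source = c("d2", "d1"),
                                      target = c("cl1", "cl1")), "sensitivity")
  g2 <- suppressWarnings(build_ds_graph(gi, mut, tgt, sens2))
  expect_identical(g$nodes, g2$nodes)
})

test_that("normalize_adjacency matches closed forms on named small graphs", {
  expect_equal(as.matrix(normalize_adjacency(matrix(0, 1, 1))),
               matrix(1, 1, 1))
  two <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(as.matrix(normalize_adjacency(two)),
               matrix(0.5, 2, 2))
  path <- matrix(0, 3, 3); path[1, 2] <- path[2, 1] <- 1
  path[2, 3] <- path[3, 2] <- 1
  Ah <- as.matrix(normalize_adjacency(path))
  expect_equal(Ah[1, 1], 1 / 2)
  expect_equal(Ah[2, 2], 1 / 3)
  expect_equal(Ah[1, 2], 1 / sqrt(6))
  expect_equal(Ah[1, 3], 0)
})

test_that("normalize_adjacency equals the entrywise oracle on small graphs", {
  withr::with_seed(11, {
    for (A in all_adjacencies(4))
      expect_equal(as.matrix(normalize_adjacency(A)), brute_normalize(A),
                   tolerance = 1e-12)
    for (i in 1:25) {
      A <- random_adjacency(6)
      expect_equal(as.matrix(normalize_adjacency(A)), brute_normalize(A),
                   tolerance = 1e-12)
    }
  })
  expect_error(normalize_adjacency(diag(3)), "zero diagonal")
})

test_that("masking removes exactly the held-out positives and round-trips", {
  gi <- gi_table(c("a", "b"), c("b", "c"))
  g <- build_gi_graph(gi)
  m <- mask_target_edges(g, "gi",
                         data.frame(source = "a", target = "b",
                                    label = "positive"))
  expect_equal(m$train_adjacency["gene:a", "gene:b"], 0)
  expect_equal(m$train_adjacency["gene:b", "gene:a"], 0)
  expect_equal(m$train_adjacency["gene:b", "gene:c"], 1)
  expect_equal(as.matrix(unmask_target_edges(m)), as.matrix(g$adjacency))

  all_masked <- mask_target_edges(g, "gi",
                                  data.frame(source = c("a", "b"),
                                             target = c("b", "c"),
                                             label = "positive"))
  expect_equal(sum(all_masked$train_adjacency), 0)
  expect_error(mask_target_edges(g, "gi",
                                 data.frame(source = "a", target = "z",
                                            label = "positive")),
               "absent")
})

test_that("graph tables round-trip through TSV", {
  gi <- gi_table(c("a", "b"), c("b", "c"))
  g <- build_gi_graph(gi)
  np <- withr::local_tempfile(fileext = ".tsv")
  ep <- withr::local_tempfile(fileext = ".tsv")
  write_graph_tables(g, np, ep)
  g2 <- read_graph_tables(np, ep)
  expect_identical(g2$nodes, g$nodes)
  expect_equal(as.matrix(g2$adjacency), as.matrix(g$adjacency))
})
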