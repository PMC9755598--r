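# End-to-end wiring: synthetic bundle -> graph variant -> ontotype features
# -> masked-edge cross-validation, for the three model variants
# (G: genetic interactions; CD: cell-line dependencies; DS: drug
# sensitivities).

#' Remove annotations by evidence code
#'
#' @param annots an `annotation_set`.
#' @param drop_evidence evidence codes to remove (default IGI, guarding
#'   against circularity in genetic-interaction prediction).
#' @return a filtered `annotation_set`.
#' @export
filter_annotations <- function(annots, drop_evidence = "IGI") {
  stopifnot(inherits(annots, "annotation_set"))
  direct <- lapply(annots$direct, function(d)
    d[!(d$evidence %in% drop_evidence), , drop = FALSE])
  direct <- direct[vapply(direct, nrow, 0L) > 0L]
  new_annotation_set(direct, annots$n_skipped_terms)
}

variant_target <- c(G = "gi", CD = "dependency", DS = "sensitivity")

#' Assemble the graph of one model variant from a benchmark bundle
#'
#' @param bundle a [make_benchmark()] bundle (or [read_benchmark()] output
#'   augmented with the same element names).
#' @param variant `"G"` (genes + GI edges), `"CD"` (+ cell lines via
#'   dependency edges) or `"DS"` (+ drugs; cell-gene edges are mutations).
#' @return a `hetero_graph`.
#' @export
benchmark_graph <- function(bundle, variant = c("G", "CD", "DS")) {
  variant <- match.arg(variant)
  # all annotated genes become nodes, including those without a GI partner,
  # so every candidate pair of the evaluation pools is scoreable
  genes <- names(bundle$annotations$direct)
  switch(variant,
    G = build_gi_graph(bundle$gi, extra_genes = genes),
    CD = build_cd_graph(bundle$gi, bundle$dependency, extra_genes = genes),
    DS = build_ds_graph(bundle$gi, bundle$mutation, bundle$drug_target,
                        bundle$sensitivity, extra_genes = genes))
}

mutations_by_cell <- function(mutation_table) {
  pos <- mutation_table[mutation_table$label == "positive", , drop = FALSE]
  lapply(split(pos$target, pos$source), function(g) sort(unique(g)))
}

targets_by_drug <- function(target_table) {
  pos <- target_table[target_table$label == "positive", , drop = FALSE]
  lapply(split(pos$target, pos$source), function(g) sort(unique(g)))
}

#' Ontotype feature matrix for a benchmark graph
#'
#' Applies the IGI evidence filter, propagates annotations to ancestors
#' (unless disabled), restricts the vocabulary to terms connected to the
#' graph, and assembles gene/cell-line/drug rows.
#'
#' @param bundle a benchmark bundle.
#' @param graph the [benchmark_graph()] of the chosen variant.
#' @param propagate propagate annotations to ancestors (the ontotype
#'   convention); set `FALSE` to use direct annotations only.
#' @param drop_evidence evidence codes removed before feature building.
#' @return sparse feature matrix aligned to the graph node order.
#' @export
benchmark_features <- function(bundle, graph, propagate = TRUE,
                               drop_evidence = "IGI") {
  annots <- filter_annotations(bundle$annotations, drop_evidence)
  gene_terms <- if (propagate) propagate_to_ancestors(annots, bundle$dag)
                else direct_terms(annots)
  build_feature_matrix(graph, gene_terms,
                       cell_mutations = mutations_by_cell(bundle$mutation),
                       drug_targets = targets_by_drug(bundle$drug_target))
}

target_pools <- function(bundle, variant) {
  target <- variant_target[[variant]]
  tab <- bundle[[target]]
  list(target_type = target,
       positives = tab[tab$label == "positive", c("source", "target")],
       candidates = tab[tab$label == "neutral", c("source", "target")])
}

#' Run the full evaluation protocol on a synthetic benchmark
#'
#' Generates a bundle, builds the variant graph and its ontotype features,
#' samples balanced negatives, constructs the cross-validation plan, and
#' runs masked-edge cross-validation (optionally with balanced-resampling
#' repetitions, repetition r drawing negatives with `seed + r`).
#'
#' @param config a [sim_config()]; its seed drives the bundle.
#' @param variant `"G"`, `"CD"` or `"DS"`.
#' @param model_config a [vgae_config()].
#' @param k fold count.
#' @param folds fold indices to evaluate (subset for quick runs).
#' @param repetitions balanced negative-resampling repetitions.
#' @param design `"edge_cv"` or `"cell_line_disjoint_cv"`.
#' @param baseline also run the ontotype random-forest baseline on the same
#'   splits.
#' @return list with `report` (VGAE `eval_report`), `baseline_report` (or
#'   `NULL`), `graph`, `features`, `plans` and `bundle`.
#' @export
run_benchmark <- function(config = sim_config(), variant = c("G", "CD", "DS"),
                          model_config = vgae_config(), k = 5,
                          folds = seq_len(k), repetitions = 1,
                          design = "edge_cv", baseline = FALSE) {
  variant <- match.arg(variant)
  bundle <- make_benchmark(config)
  graph <- benchmark_graph(bundle, variant)
  X <- benchmark_features(bundle, graph)
  pools <- target_pools(bundle, variant)

  reports <- list(); base_reports <- list(); plans <- list()
  for (r in seq_len(repetitions)) {
    negs <- balanced_negatives(pools$positives, pools$candidates,
                               seed = config$seed + r)
    plan <- make_folds(pools$positives, negs, k = k,
                       seed = config$seed + 17L * r, design = design,
                       target_type = pools$target_type)
    plans[[r]] <- plan
    cfg <- model_config
    cfg$seed <- model_config$seed + 101L * (r - 1L)
    reports[[r]] <- cross_validate(graph, X, plan, pools$target_type,
                                   config = cfg, folds = folds,
                                   tag = paste0("vgae_", variant))
    if (baseline)
      base_reports[[r]] <- rf_baseline(X, plan, pools$target_type,
                                       folds = folds,
                                       seed = config$seed + 101L * r)
  }
  list(report = combine_reports(reports),
       baseline_report = if (baseline) combine_reports(base_reports),
       graph = graph, features = X, plans = plans, bundle = bundle)
}
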