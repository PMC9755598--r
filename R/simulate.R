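# Synthetic benchmark with a planted, tunable signal. The generator emulates
# the real inputs end to end: a GO-like term tree (OBO), leaf-biased gene
# annotations with mixed evidence codes (GAF), and the four edge sets, with
# edge probabilities driven by ontotype similarity so that signal recovery is
# a quantitative test surface.

#' Configuration of the synthetic benchmark
#'
#' Genes are organized into `n_modules` functional modules; each module owns
#' a pool of `terms_per_gene + 2` leaf terms and every member gene is
#' annotated with `terms_per_gene` terms drawn from its module pool. Pairs of
#' nodes with similar term supports then receive edges with elevated
#' probability \eqn{p = \alpha + (1-\alpha)(1 - e^{-\beta s})}, where s is
#' the Jaccard similarity of the supports: \eqn{\beta = 0} is pure noise at
#' rate \eqn{\alpha}; large \eqn{\beta} saturates p toward 1 for similar
#' pairs.
#'
#' @param n_terms number of ontology terms.
#' @param dag_branching maximum children per term in the random term tree.
#' @param n_genes,n_cell_lines,n_drugs entity counts.
#' @param terms_per_gene direct annotations per gene.
#' @param mutations_per_cell mutated genes per cell line (drawn uniformly).
#' @param targets_per_drug target genes per drug (drawn uniformly).
#' @param n_modules number of planted gene modules.
#' @param signal_strength beta >= 0, the similarity-to-probability gain.
#' @param base_rate alpha in (0, 1), the background edge probability.
#' @param seed integer master seed; the full bundle is a pure function of
#'   (config, seed).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_terms = 240, dag_branching = 3, n_genes = 300,
                       terms_per_gene = 6, n_cell_lines = 30,
                       mutations_per_cell = 2, n_drugs = 20,
                       targets_per_drug = 2, n_modules = 15,
                       signal_strength = 4, base_rate = 0.02, seed = 1) {
  cfg <- list(n_terms = n_terms, dag_branching = dag_branching,
              n_genes = n_genes, terms_per_gene = terms_per_gene,
              n_cell_lines = n_cell_lines,
              mutations_per_cell = mutations_per_cell, n_drugs = n_drugs,
              targets_per_drug = targets_per_drug, n_modules = n_modules,
              signal_strength = signal_strength, base_rate = base_rate,
              seed = seed)
  counts <- cfg[c("n_terms", "dag_branching", "n_genes", "terms_per_gene",
                  "n_cell_lines", "mutations_per_cell", "n_drugs",
                  "targets_per_drug", "n_modules")]
  if (any(unlist(counts) < 1)) stop_ol("all counts must be positive")
  if (base_rate <= 0 || base_rate >= 1) stop_ol("base_rate must be in (0, 1)")
  if (signal_strength < 0) stop_ol("signal_strength must be >= 0")
  if (terms_per_gene > n_terms) stop_ol("terms_per_gene exceeds n_terms")
  structure(cfg, class = "sim_config")
}

sim_ids <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))

#' Generate a random rooted term tree
#'
#' Every non-root term receives one parent among the earlier terms, chosen
#' uniformly among terms that still have fewer than `dag_branching` children;
#' namespaces are assigned round-robin across the three GO namespaces. The
#' serialized OBO ([write_obo()]) re-parses to the identical DAG.
#'
#' @param config a [sim_config()].
#' @return an `ontology_dag`.
#' @export
make_ontology <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_terms
  ids <- sim_ids("T", n)
  withr::with_seed(config$seed, {
    parents <- setNames(vector("list", n), ids)
    parents[[1L]] <- character()
    n_children <- integer(n)
    for (i in seq_len(n)[-1L]) {
      open <- which(n_children[seq_len(i - 1L)] < config$dag_branching)
      p <- if (length(open) == 1L) open else sample(open, 1L)
      parents[[i]] <- ids[[p]]
      n_children[[p]] <- n_children[[p]] + 1L
    }
    ns <- rep_len(c("biological_process", "cellular_component",
                    "molecular_function"), n)
    new_ontology_dag(ids, parents, setNames(ns, ids),
                     setNames(paste("synthetic term", seq_len(n)), ids))
  })
}

# leaf terms (no children), padded with the last-created terms if scarce
leaf_terms <- function(dag) {
  with_children <- unique(unlist(dag$parents, use.names = FALSE))
  leaves <- setdiff(dag$terms, with_children)
  if (length(leaves) < 2L) dag$terms else leaves
}

module_pools <- function(dag, config) {
  if (config$n_modules * config$terms_per_gene > config$n_terms)
    stop_ol("n_modules * terms_per_gene exceeds n_terms; no disjoint pools")
  pool_size <- max(config$terms_per_gene,
                   min(config$terms_per_gene + 2L,
                       config$n_terms %/% config$n_modules))
  need <- config$n_modules * pool_size
  leaves <- leaf_terms(dag)
  if (length(leaves) < need) {
    # pad with the deepest non-leaf terms (later ids are deeper on average)
    extra <- setdiff(rev(dag$terms), leaves)
    leaves <- c(leaves, extra[seq_len(min(length(extra), need - length(leaves)))])
  }
  if (length(leaves) < need)
    stop_ol("not enough terms for ", config$n_modules, " modules of pool size ",
            pool_size, "; increase n_terms")
  chosen <- sample(leaves, need)
  split(chosen, rep(seq_len(config$n_modules), each = pool_size))
}

#' Generate leaf-biased gene annotations with mixed evidence codes
#'
#' Each gene belongs to one planted module and draws `terms_per_gene` terms
#' without replacement from the module's leaf-term pool. Evidence codes are
#' drawn from IDA/IMP/IGI with proportions 0.6/0.3/0.1, so the IGI filter of
#' [parse_annotations()] is exercised on about 10 percent of the rows.
#'
#' @param dag an `ontology_dag` from [make_ontology()].
#' @param config a [sim_config()].
#' @return an `annotation_set` with attributes `module` (named integer vector
#'   gene -> module) and `pools` (list of module term pools).
#' @export
make_annotations <- function(dag, config) {
  stopifnot(inherits(dag, "ontology_dag"), inherits(config, "sim_config"))
  genes <- sim_ids("g", config$n_genes)
  withr::with_seed(config$seed + 1L, {
    pools <- module_pools(dag, config)
    module <- setNames(sample(rep_len(seq_len(config$n_modules), config$n_genes)),
                       genes)
    direct <- lapply(genes, function(g) {
      terms <- sample(pools[[module[[g]]]], config$terms_per_gene)
      ev <- sample(c("IDA", "IMP", "IGI"), config$terms_per_gene,
                   replace = TRUE, prob = c(0.6, 0.3, 0.1))
      d <- data.frame(term = terms, evidence = ev, stringsAsFactors = FALSE)
      d[order(d$term), , drop = FALSE]
    })
    names(direct) <- genes
    out <- new_annotation_set(direct)
    attr(out, "module") <- module
    attr(out, "pools") <- pools
    out
  })
}

# binary support matrix (items x terms) from a named list of term sets
support_matrix <- function(term_sets, terms) {
  items <- names(term_sets)
  j <- lapply(term_sets, function(ts) match(intersect(ts, terms), terms))
  Matrix::sparseMatrix(i = rep(seq_along(items), lengths(j)),
                       j = unlist(j, use.names = FALSE), x = 1,
                       dims = c(length(items), length(terms)),
                       dimnames = list(items, terms))
}

#' Plant edges with similarity-dependent probability
#'
#' For every candidate pair the similarity s is the Jaccard index of the
#' nonzero term supports of the two endpoint feature rows; the pair becomes
#' a positive edge with probability
#' \eqn{p = \alpha + (1-\alpha)(1 - e^{-\beta s})} and is labeled neutral
#' otherwise. With \eqn{\beta = 0} edges are pure noise at rate
#' \eqn{\alpha}; disjoint supports give exactly \eqn{p = \alpha}; identical
#' supports approach p = 1 for large \eqn{\beta}.
#'
#' @param rows feature matrix (dense or sparse) with item ids as rownames.
#' @param pairs data.frame with `source`, `target` item ids (rownames of
#'   `rows`).
#' @param alpha base rate in (0, 1).
#' @param beta signal strength >= 0.
#' @param seed integer seed for the Bernoulli draws.
#' @param edge_type edge type of the resulting table.
#' @return list with `table` (an `edge_table`; `score` column carries the
#'   generating probability) and `truth` (data.frame with per-pair
#'   `similarity`, `probability`, `label`).
#' @export
plant_edges <- function(rows, pairs, alpha, beta, seed = 1,
                        edge_type = "gi") {
  if (alpha <= 0 || alpha >= 1) stop_ol("alpha must be in (0, 1)")
  if (beta < 0) stop_ol("beta must be >= 0")
  B <- Matrix::Matrix(rows != 0, sparse = TRUE) * 1
  sizes <- Matrix::rowSums(B)
  inter_all <- as.matrix(Matrix::tcrossprod(B))
  i <- match(as.character(pairs$source), rownames(rows))
  j <- match(as.character(pairs$target), rownames(rows))
  if (anyNA(i) || anyNA(j)) stop_ol("pair references unknown feature row")
  inter <- inter_all[cbind(i, j)]
  union <- sizes[i] + sizes[j] - inter
  s <- ifelse(union > 0, inter / union, 0)
  p <- alpha + (1 - alpha) * (1 - exp(-beta * s))
  lab <- withr::with_seed(seed, rbinom(length(p), 1L, p))
  truth <- data.frame(source = as.character(pairs$source),
                      target = as.character(pairs$target),
                      similarity = s, probability = p,
                      label = ifelse(lab == 1L, "positive", "neutral"),
                      stringsAsFactors = FALSE)
  tab <- new_edge_table(data.frame(source = truth$source, target = truth$target,
                                   label = truth$label, score = round(p, 6),
                                   p_value = NA_real_,
                                   stringsAsFactors = FALSE),
                        edge_type)
  list(table = tab, truth = truth)
}

all_pairs <- function(a, b = NULL) {
  if (is.null(b)) {
    idx <- which(upper.tri(matrix(0, length(a), length(a))), arr.ind = TRUE)
    data.frame(source = a[idx[, 1L]], target = a[idx[, 2L]],
               stringsAsFactors = FALSE)
  } else {
    expand.grid(source = a, target = b, stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE)[, c("source", "target")]
  }
}

#' Generate the full synthetic benchmark bundle
#'
#' Produces the ontology, the annotations and all edge sets of the
#' three-part model graph: gene-gene GI edges planted on ontotype similarity,
#' random cell-line mutations, signal-bearing cell-gene dependency edges,
#' random drug targets, and drug-cell sensitivity edges planted on the
#' similarity between drug target-set supports and cell-line mutation-set
#' supports. Similarities use the direct (unpropagated) term supports so the
#' shared root lineage does not put a floor under every pair's probability.
#'
#' @param config a [sim_config()].
#' @return a `sim_bundle`: list with `config`, `dag`, `annotations` (IGI rows
#'   included; the model filters them), edge tables `gi`, `dependency`,
#'   `mutation`, `drug_target`, `sensitivity`, and `truth` (per-edge-set
#'   generating similarities and probabilities).
#' @export
make_benchmark <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  dag <- make_ontology(config)
  annots <- make_annotations(dag, config)
  genes <- names(annots$direct)
  gene_support <- support_matrix(direct_terms(annots), dag$terms)

  alpha <- config$base_rate; beta <- config$signal_strength

  gi <- plant_edges(gene_support, all_pairs(genes), alpha, beta,
                    seed = config$seed + 2L, edge_type = "gi")

  cells <- sim_ids("cl", config$n_cell_lines)
  cell_mut <- withr::with_seed(config$seed + 3L,
    setNames(lapply(cells, function(cl)
      sort(sample(genes, config$mutations_per_cell))), cells))
  mutation <- new_edge_table(
    data.frame(source = rep(cells, lengths(cell_mut)),
               target = unlist(cell_mut, use.names = FALSE),
               label = "positive", stringsAsFactors = FALSE),
    "mutation")

  cell_support <- support_matrix(
    lapply(cell_mut, function(gs)
      sort(unique(unlist(direct_terms(annots)[gs], use.names = FALSE)))),
    dag$terms)

  cg_rows <- rbind(cell_support, gene_support)
  dependency <- plant_edges(cg_rows, all_pairs(cells, genes), alpha, beta,
                            seed = config$seed + 4L, edge_type = "dependency")

  drugs <- sim_ids("d", config$n_drugs)
  drug_tgt <- withr::with_seed(config$seed + 5L,
    setNames(lapply(drugs, function(d)
      sort(sample(genes, config$targets_per_drug))), drugs))
  drug_target <- new_edge_table(
    data.frame(source = rep(drugs, lengths(drug_tgt)),
               target = unlist(drug_tgt, use.names = FALSE),
               label = "positive", stringsAsFactors = FALSE),
    "drug_target")

  drug_support <- support_matrix(
    lapply(drug_tgt, function(gs)
      sort(unique(unlist(direct_terms(annots)[gs], use.names = FALSE)))),
    dag$terms)

  dc_rows <- rbind(drug_support, cell_support)
  sensitivity <- plant_edges(dc_rows, all_pairs(drugs, cells), alpha, beta,
                             seed = config$seed + 6L, edge_type = "sensitivity")

  structure(list(config = config, dag = dag, annotations = annots,
                 gi = gi$table, dependency = dependency$table,
                 mutation = mutation, drug_target = drug_target,
                 sensitivity = sensitivity$table,
                 cell_mutations = cell_mut, drug_targets = drug_tgt,
                 truth = list(gi = gi$truth, dependency = dependency$truth,
                              sensitivity = sensitivity$truth)),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cfg <- x$config
  cat("sim_bundle: ", cfg$n_genes, " genes, ", cfg$n_cell_lines,
      " cell lines, ", cfg$n_drugs, " drugs; beta=", cfg$signal_strength,
      ", alpha=", cfg$base_rate, ", seed=", cfg$seed, "\n", sep = "")
  for (nm in c("gi", "dependency", "mutation", "drug_target", "sensitivity"))
    cat(sprintf("  %-12s %6d pairs, %6d positive\n", nm, nrow(x[[nm]]),
                sum(x[[nm]]$label == "positive")))
  invisible(x)
}

#' Write a benchmark bundle to a directory
#'
#' Emits `ontology.obo`, `annotations.gaf`, one TSV per edge set, and a
#' `manifest.json` holding the generating configuration. All files re-parse
#' through the package readers; the bundle is byte-identical for identical
#' (config, seed).
#'
#' @param bundle a [make_benchmark()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_obo(bundle$dag, file.path(dir, "ontology.obo"))
  write_gaf(bundle$annotations, file.path(dir, "annotations.gaf"))
  for (nm in c("gi", "dependency", "mutation", "drug_target", "sensitivity"))
    write_edge_table(bundle[[nm]], file.path(dir, paste0(nm, ".tsv")))
  jsonlite::write_json(unclass(bundle$config), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a benchmark bundle directory written by [write_benchmark()]
#'
#' @param dir bundle directory.
#' @return list with `config`, `dag`, `annotations` (unfiltered: IGI rows
#'   kept so the caller controls filtering) and the five edge tables.
#' @export
read_benchmark <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  dag <- parse_obo(file.path(dir, "ontology.obo"))
  annots <- parse_annotations(file.path(dir, "annotations.gaf"), dag,
                              drop_evidence = character())
  tabs <- lapply(setNames(nm = c("gi", "dependency", "mutation",
                                 "drug_target", "sensitivity")),
                 function(nm) read_edge_table(file.path(dir, paste0(nm, ".tsv")), nm))
  c(list(config = do.call(sim_config, cfg), dag = dag, annotations = annots),
    tabs)
}
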