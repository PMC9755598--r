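# Heterogeneous graph assembly. The model graph is built in three parts:
# genes linked by genetic interactions (VGAE_G); plus cell lines linked to
# genes by dependency relations (VGAE_CD); plus drugs linked to genes by
# drug-target relations and to cell lines by the sensitivity links that are
# the prediction target (VGAE_DS; cell-gene links are mutations there).

# allowed (unordered) node-type patterns per edge type
edge_pattern_ok <- function(edge_type, type_a, type_b) {
  want <- sort(edge_schema(edge_type))
  identical(sort(c(type_a, type_b)), want)
}

new_hetero_graph <- function(nodes, edges, neutrals = NULL) {
  # canonical node order: genes sorted, then cell lines, then drugs
  type_rank <- c(gene = 1L, cell_line = 2L, drug = 3L)
  nodes <- unique(nodes)
  nodes <- nodes[order(type_rank[nodes$type], nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  if (anyDuplicated(nodes$id))
    stop_ol("duplicate node id after namespacing: ",
            nodes$id[duplicated(nodes$id)][1L])

  node_type <- setNames(nodes$type, nodes$id)
  if (nrow(edges) > 0L) {
    missing <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(missing) > 0L)
      stop_ol("edge endpoint(s) not in node set: ", paste(head(missing, 3), collapse = ", "))
    ok <- mapply(edge_pattern_ok, edges$edge_type,
                 node_type[edges$source], node_type[edges$target])
    if (!all(ok))
      stop_ol("edge with node-type pattern violating its edge_type: row ",
              which(!ok)[1L])
    if (any(edges$source == edges$target))
      stop_ol("self-pair edges are not allowed")
    cp <- canonical_pair(edges$source, edges$target)
    edges$source <- cp$source; edges$target <- cp$target
    edges <- unique(edges)
  }
  rownames(edges) <- NULL

  n <- nrow(nodes)
  idx <- setNames(seq_len(n), nodes$id)
  A <- Matrix::sparseMatrix(i = c(idx[edges$source], idx[edges$target]),
                            j = c(idx[edges$target], idx[edges$source]),
                            x = 1, dims = c(n, n),
                            dimnames = list(nodes$id, nodes$id))
  A@x[] <- 1  # collapse any duplicate triplets to binary
  structure(list(nodes = nodes, adjacency = A, edges = edges,
                 neutrals = neutrals),
            class = "hetero_graph")
}

#' @export
print.hetero_graph <- function(x, ...) {
  tt <- table(factor(x$nodes$type, levels = c("gene", "cell_line", "drug")))
  cat("hetero_graph: ", nrow(x$nodes), " nodes (",
      paste(names(tt), tt, sep = "=", collapse = ", "), "), ",
      nrow(x$edges), " edges\n", sep = "")
  et <- table(x$edges$edge_type)
  if (length(et)) cat("  edge types:",
                      paste(names(et), et, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

edges_from_table <- function(et, edge_type = attr(et, "edge_type")) {
  schema <- edge_schema(edge_type)
  pos <- et[et$label == "positive", , drop = FALSE]
  data.frame(source = ns_id(pos$source, schema[[1L]]),
             target = ns_id(pos$target, schema[[2L]]),
             edge_type = rep(edge_type, nrow(pos)),
             stringsAsFactors = FALSE)
}

neutrals_from_table <- function(et, edge_type = attr(et, "edge_type")) {
  schema <- edge_schema(edge_type)
  neu <- et[et$label == "neutral", , drop = FALSE]
  data.frame(source = ns_id(neu$source, schema[[1L]]),
             target = ns_id(neu$target, schema[[2L]]),
             edge_type = rep(edge_type, nrow(neu)),
             stringsAsFactors = FALSE)
}

nodes_from_table <- function(et) {
  schema <- edge_schema(attr(et, "edge_type"))
  data.frame(id = c(ns_id(et$source, schema[[1L]]), ns_id(et$target, schema[[2L]])),
             type = c(rep(schema[[1L]], nrow(et)), rep(schema[[2L]], nrow(et))),
             stringsAsFactors = FALSE)
}

#' Build the genetic-interaction graph (gene nodes only)
#'
#' Nodes are the genes appearing in positive GI pairs (plus any genes in
#' `extra_genes`, e.g. annotated genes without a GI partner); edges are the
#' positive GI pairs. Neutral pairs are excluded from the adjacency but kept
#' on the graph as the evaluation-negative pool.
#'
#' @param gi an `edge_table` of type `"gi"`.
#' @param extra_genes optional character vector of additional (isolated) gene
#'   ids to include as nodes.
#' @return a `hetero_graph`.
#' @export
build_gi_graph <- function(gi, extra_genes = character()) {
  stopifnot(inherits(gi, "edge_table"), attr(gi, "edge_type") == "gi")
  if (!any(gi$label == "positive"))
    stop_ol("no positive GI pairs: cannot build a GI graph")
  pos <- gi[gi$label == "positive", , drop = FALSE]
  nodes <- data.frame(id = ns_id(unique(c(pos$source, pos$target, extra_genes)), "gene"),
                      type = "gene", stringsAsFactors = FALSE)
  new_hetero_graph(nodes, edges_from_table(gi), neutrals_from_table(gi))
}

#' Build the cell-line dependency graph (genes + cell lines)
#'
#' Gene-gene edges come from positive GI pairs; cell-gene edges from positive
#' dependency pairs. The node universe is the union of both tables; a cell
#' line with no positive dependency is kept as an isolated node with a
#' warning. An empty GI table degrades to a bipartite cell-gene graph with a
#' warning.
#'
#' @param gi an `edge_table` of type `"gi"` (may have zero positives).
#' @param dependency an `edge_table` of type `"dependency"`.
#' @param extra_genes optional isolated genes to include.
#' @return a `hetero_graph`.
#' @export
build_cd_graph <- function(gi, dependency, extra_genes = character()) {
  stopifnot(inherits(dependency, "edge_table"),
            attr(dependency, "edge_type") == "dependency")
  gi_edges <- if (is.null(gi) || !any(gi$label == "positive")) {
    warning("no positive GI pairs: building a bipartite cell-gene graph")
    NULL
  } else edges_from_table(gi)

  cells <- unique(dependency$source)
  lonely <- setdiff(cells, dependency$source[dependency$label == "positive"])
  if (length(lonely) > 0L)
    warning(length(lonely), " cell line(s) with zero positive dependency ",
            "edges kept as isolated nodes")

  nodes <- rbind(
    if (!is.null(gi)) nodes_from_table(gi),
    nodes_from_table(dependency),
    data.frame(id = ns_id(extra_genes, "gene"),
               type = rep("gene", length(extra_genes)), stringsAsFactors = FALSE))
  edges <- rbind(gi_edges, edges_from_table(dependency))
  new_hetero_graph(nodes, edges,
                   rbind(if (!is.null(gi)) neutrals_from_table(gi),
                         neutrals_from_table(dependency)))
}

#' Build the drug-sensitivity graph (genes + cell lines + drugs)
#'
#' Gene-gene edges from positive GI pairs, cell-gene edges from mutations,
#' drug-gene edges from drug targets, and drug-cell edges from positive
#' sensitivity pairs (the prediction target). Drugs without targets and cell
#' lines without mutations are kept with a warning.
#'
#' @param gi `edge_table` of type `"gi"`.
#' @param mutations `edge_table` of type `"mutation"` (cell-gene).
#' @param targets `edge_table` of type `"drug_target"` (drug-gene).
#' @param sensitivity `edge_table` of type `"sensitivity"` (drug-cell).
#' @param extra_genes optional isolated genes to include.
#' @return a `hetero_graph`.
#' @export
build_ds_graph <- function(gi, mutations, targets, sensitivity,
                           extra_genes = character()) {
  stopifnot(attr(mutations, "edge_type") == "mutation",
            attr(targets, "edge_type") == "drug_target",
            attr(sensitivity, "edge_type") == "sensitivity")
  drugs <- unique(sensitivity$source)
  no_target <- setdiff(drugs, targets$source[targets$label == "positive"])
  if (length(no_target) > 0L)
    warning(length(no_target), " drug(s) in the sensitivity table have no ",
            "target edge; kept as nodes")

  nodes <- rbind(nodes_from_table(gi), nodes_from_table(mutations),
                 nodes_from_table(targets), nodes_from_table(sensitivity),
                 data.frame(id = ns_id(extra_genes, "gene"),
                            type = rep("gene", length(extra_genes)),
                            stringsAsFactors = FALSE))
  edges <- rbind(edges_from_table(gi), edges_from_table(mutations),
                 edges_from_table(targets), edges_from_table(sensitivity))
  new_hetero_graph(nodes, edges,
                   rbind(neutrals_from_table(gi),
                         neutrals_from_table(sensitivity)))
}

#' Symmetrically normalized adjacency with self-loops
#'
#' Computes the GCN propagation operator
#' \eqn{\hat A = \bar D^{-1/2}(A + I)\bar D^{-1/2}} where \eqn{\bar D} is the
#' diagonal degree matrix of \eqn{A + I}. The result is symmetric, entrywise
#' non-negative, and has spectral radius at most 1.
#'
#' @param A a symmetric binary adjacency with zero diagonal (a base matrix, a
#'   sparse Matrix, or a `hetero_graph` whose adjacency is used).
#' @return a sparse symmetric matrix of the same dimension.
#' @export
normalize_adjacency <- function(A) {
  if (inherits(A, "hetero_graph")) A <- A$adjacency
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  if (!Matrix::isSymmetric(A, check.attributes = FALSE))
    stop_ol("adjacency must be symmetric")
  if (any(Matrix::diag(A) != 0))
    stop_ol("adjacency must have a zero diagonal (self-loops are added internally)")
  Abar <- A + Matrix::Diagonal(nrow(A))
  dinv <- 1 / sqrt(Matrix::rowSums(Abar))
  Ahat <- Matrix::Diagonal(x = dinv) %*% Abar %*% Matrix::Diagonal(x = dinv)
  dimnames(Ahat) <- dimnames(A)
  methods::as(Ahat, "CsparseMatrix")
}

#' Mask held-out target edges out of the training adjacency
#'
#' Zeroes both triangle entries of every held-out positive pair of the target
#' edge type, leaving every other edge type intact; the held-out pairs
#' (positives plus supplied negatives) are kept aside for scoring.
#'
#' @param graph a `hetero_graph`.
#' @param target_type the edge type being predicted.
#' @param heldout data.frame with columns `source`, `target` (raw ids, in the
#'   `target_type` schema order) and `label` (`"positive"`/`"neutral"`).
#' @return a `masked_graph`: list with `graph`, `target_type`,
#'   `train_adjacency`, and `heldout` (with namespaced ids).
#' @export
mask_target_edges <- function(graph, target_type, heldout) {
  stopifnot(inherits(graph, "hetero_graph"), target_type %in% EDGE_TYPES)
  schema <- edge_schema(target_type)
  heldout <- data.frame(source = ns_id(as.character(heldout$source), schema[[1L]]),
                        target = ns_id(as.character(heldout$target), schema[[2L]]),
                        label = as.character(heldout$label),
                        stringsAsFactors = FALSE)
  missing <- setdiff(c(heldout$source, heldout$target), graph$nodes$id)
  if (length(missing) > 0L)
    stop_ol("held-out pair references node(s) absent from the graph: ",
            paste(head(missing, 3), collapse = ", "))

  A <- graph$adjacency
  pos <- heldout[heldout$label == "positive", , drop = FALSE]
  if (nrow(pos) > 0L) {
    i <- match(pos$source, graph$nodes$id)
    j <- match(pos$target, graph$nodes$id)
    if (any(A[cbind(i, j)] == 0))
      stop_ol("held-out positive pair is not an edge of the graph")
    A[cbind(i, j)] <- 0
    A[cbind(j, i)] <- 0
    A <- Matrix::drop0(A)
  }
  structure(list(graph = graph, target_type = target_type,
                 train_adjacency = A, heldout = heldout),
            class = "masked_graph")
}

#' Restore the original adjacency of a masked graph
#'
#' @param masked a `masked_graph`.
#' @return the original adjacency matrix (masking round-trips exactly).
#' @export
unmask_target_edges <- function(masked) {
  stopifnot(inherits(masked, "masked_graph"))
  masked$graph$adjacency
}

#' Save a heterogeneous graph as two TSV files
#'
#' @param graph a `hetero_graph`.
#' @param node_path,edge_path output paths for the node table (`id`, `type`)
#'   and the edge table (`source`, `target`, `edge_type`).
#' @return `graph`, invisibly.
#' @export
write_graph_tables <- function(graph, node_path, edge_path) {
  stopifnot(inherits(graph, "hetero_graph"))
  write.table(graph$nodes, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(graph$edges, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(graph)
}

#' Load a heterogeneous graph written by [write_graph_tables()]
#'
#' @param node_path,edge_path TSV paths.
#' @return a `hetero_graph` with the canonical node order.
#' @export
read_graph_tables <- function(node_path, edge_path) {
  nodes <- read.delim(node_path, stringsAsFactors = FALSE)
  edges <- read.delim(edge_path, stringsAsFactors = FALSE)
  new_hetero_graph(nodes, edges)
}
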