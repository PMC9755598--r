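# Ontotype features: GO-term vectors for genes, cell lines and drugs.
#
# A gene is a binary vector over retained GO terms; a gene set (a cell line's
# mutated genes, a drug's targets) is the sum of its member gene vectors
# divided by the set size, so entries stay in [0, 1]. All node types share one
# feature dimension.

#' Propagate direct annotations to all ancestors (true-path rule)
#'
#' Each gene's term set becomes the union of its direct terms and every
#' ancestor reachable through is_a/part_of parent links. The result is a
#' fixed point: propagating twice changes nothing.
#'
#' @param direct an [annotation_set][parse_annotations], or a named list
#'   mapping gene id to a character vector of directly annotated terms.
#' @param dag an [ontology_dag][parse_obo] (must be acyclic).
#' @return named list mapping gene id to a sorted character vector of terms.
#' @export
propagate_to_ancestors <- function(direct, dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (inherits(direct, "annotation_set")) direct <- direct_terms(direct)
  anc <- ancestor_closure(dag)
  lapply(direct, function(terms) {
    if (length(terms) == 0L) return(character())
    sort(unique(c(terms, unlist(anc[terms], use.names = FALSE))))
  })
}

# term -> all (strict) ancestors, memoized bottom-up
ancestor_closure <- function(dag) {
  anc <- setNames(vector("list", length(dag$terms)), dag$terms)
  done <- setNames(logical(length(dag$terms)), dag$terms)
  get_anc <- function(t) {
    if (done[[t]]) return(anc[[t]])
    ps <- dag$parents[[t]]
    out <- ps
    for (p in ps) out <- c(out, get_anc(p))
    out <- unique(out)
    anc[[t]] <<- out
    done[[t]] <<- TRUE
    out
  }
  for (t in dag$terms) get_anc(t)
  anc
}

#' Build the retained term vocabulary
#'
#' Retains exactly the terms connected to at least one node of the model
#' graph: terms of gene nodes, terms of any graph cell line's mutated genes,
#' and terms of any graph drug's target genes. Terms annotated only to genes
#' absent from the graph are excluded. Ordering is lexicographic, hence
#' deterministic.
#'
#' @param gene_terms named list gene -> propagated term set
#'   (from [propagate_to_ancestors()]).
#' @param graph_genes character vector of gene ids that are graph nodes.
#' @param cell_mutations named list cell line -> mutated gene ids (optional).
#' @param drug_targets named list drug -> target gene ids (optional).
#' @return a `term_vocabulary`: list with `terms` (ordered character vector)
#'   and `index` (named integer vector term -> column).
#' @export
build_vocabulary <- function(gene_terms, graph_genes,
                             cell_mutations = list(), drug_targets = list()) {
  used_genes <- unique(c(graph_genes,
                         unlist(cell_mutations, use.names = FALSE),
                         unlist(drug_targets, use.names = FALSE)))
  terms <- sort(unique(unlist(gene_terms[intersect(used_genes, names(gene_terms))],
                              use.names = FALSE)))
  if (length(terms) == 0L)
    stop_ol("empty term vocabulary: no retained term is connected to any node")
  structure(list(terms = terms,
                 index = setNames(seq_along(terms), terms)),
            class = "term_vocabulary")
}

#' @export
print.term_vocabulary <- function(x, ...) {
  cat("term_vocabulary:", length(x$terms), "retained terms\n")
  invisible(x)
}

#' Binary ontotype vector of one gene
#'
#' @param gene gene id.
#' @param gene_terms named list gene -> propagated term set.
#' @param vocab a [build_vocabulary()] result.
#' @return numeric 0/1 vector of length `length(vocab$terms)`. A gene absent
#'   from `gene_terms` yields an all-zero row with a warning.
#' @export
gene_vector <- function(gene, gene_terms, vocab) {
  v <- numeric(length(vocab$terms))
  terms <- gene_terms[[gene]]
  if (is.null(terms)) {
    warning("gene '", gene, "' has no annotations; all-zero feature row")
    return(v)
  }
  idx <- vocab$index[intersect(terms, vocab$terms)]
  v[idx] <- 1
  v
}

#' Normalized ontotype vector of a gene set
#'
#' The sum of the member gene vectors divided by the number of genes in the
#' set, so that entries lie in \[0, 1\]. An empty set yields a zero row.
#'
#' @param genes character vector of member gene ids.
#' @inheritParams gene_vector
#' @return numeric vector of length `length(vocab$terms)`.
#' @export
set_vector <- function(genes, gene_terms, vocab) {
  genes <- unique(genes)
  if (length(genes) == 0L) return(numeric(length(vocab$terms)))
  v <- numeric(length(vocab$terms))
  for (g in genes) {
    terms <- gene_terms[[g]]
    if (is.null(terms)) next
    idx <- vocab$index[intersect(terms, vocab$terms)]
    v[idx] <- v[idx] + 1
  }
  v / length(genes)
}

#' Assemble the node-by-term feature matrix of a heterogeneous graph
#'
#' Row i corresponds to graph node i: a binary gene vector for gene nodes,
#' the normalized set vector of its mutated genes for cell-line nodes, and of
#' its target genes for drug nodes. Stored sparse.
#'
#' @param graph a [hetero_graph][build_gi_graph].
#' @param gene_terms named list gene -> propagated term set.
#' @param cell_mutations named list cell line -> mutated gene ids.
#' @param drug_targets named list drug -> target gene ids.
#' @param vocab optional [build_vocabulary()] result; built from the graph
#'   when `NULL`.
#' @return a sparse `dgCMatrix` (nodes x terms) with node ids as rownames and
#'   terms as colnames.
#' @export
build_feature_matrix <- function(graph, gene_terms, cell_mutations = list(),
                                 drug_targets = list(), vocab = NULL) {
  stopifnot(inherits(graph, "hetero_graph"))
  nodes <- graph$nodes
  if (is.null(vocab))
    vocab <- build_vocabulary(gene_terms, strip_ns(nodes$id[nodes$type == "gene"]),
                              cell_mutations, drug_targets)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (i in seq_len(nrow(nodes))) {
    raw <- strip_ns(nodes$id[[i]])
    v <- switch(nodes$type[[i]],
      gene      = gene_vector(raw, gene_terms, vocab),
      cell_line = set_vector(cell_mutations[[raw]] %||% character(), gene_terms, vocab),
      drug      = set_vector(drug_targets[[raw]] %||% character(), gene_terms, vocab),
      stop_ol("node '", nodes$id[[i]], "' has unknown type '", nodes$type[[i]], "'"))
    nz <- which(v != 0)
    rows <- c(rows, rep.int(i, length(nz)))
    cols <- c(cols, nz)
    vals <- c(vals, v[nz])
  }
  X <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(nrow(nodes), length(vocab$terms)),
                            dimnames = list(nodes$id, vocab$terms))
  methods::as(X, "CsparseMatrix")
}

#' Fraction of zero entries of a feature row or matrix
#'
#' For a pair of nodes, pair sparsity is defined as the sparsity of the
#' elementwise sum of their two rows (see [pair_sparsity()]).
#'
#' @param x numeric vector, matrix or sparse Matrix.
#' @return fraction of entries equal to zero, in \[0, 1\].
#' @export
sparsity <- function(x) {
  n <- length(x)
  if (n == 0L) stop_ol("sparsity of an empty matrix is undefined")
  if (methods::is(x, "sparseMatrix")) {
    1 - Matrix::nnzero(x) / n
  } else {
    sum(x == 0) / n
  }
}

#' Pair sparsity of two feature rows
#'
#' @param X feature matrix with node ids as rownames.
#' @param i,j node ids or row indices.
#' @return sparsity of the elementwise sum of rows i and j.
#' @export
pair_sparsity <- function(X, i, j) {
  sparsity(as.numeric(X[i, ]) + as.numeric(X[j, ]))
}
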