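# Shared fixtures and independent oracles, built in code.

# --- tiny OBO documents ------------------------------------------------------

obo_lines <- function(terms) {
  # terms: list of lists with id, is_a (chr vec), part_of (chr vec),
  # obsolete (lgl), namespace
  out <- c("format-version: 1.2", "")
  for (t in terms) {
    out <- c(out, "[Term]", paste0("id: ", t$id))
    if (!is.null(t$namespace)) out <- c(out, paste0("namespace: ", t$namespace))
    for (p in t$is_a %||% character()) out <- c(out, paste0("is_a: ", p))
    for (p in t$part_of %||% character())
      out <- c(out, paste0("relationship: part_of ", p))
    if (isTRUE(t$obsolete)) out <- c(out, "is_obsolete: true")
    out <- c(out, "")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_dag <- function() {
  parse_obo(obo_lines(list(
    list(id = "t1", namespace = "biological_process"),
    list(id = "t2", is_a = "t1"),
    list(id = "t3", part_of = "t1"),
    list(id = "t4", is_a = "t2"))))
}

gaf_line <- function(gene, term, evidence) {
  row <- rep("", 17)
  row[1] <- "DB"; row[2] <- gene; row[3] <- gene; row[5] <- term
  row[6] <- "DB:1"; row[7] <- evidence; row[9] <- "P"
  paste(row, collapse = "\t")
}

# --- small synthetic world for protocol tests --------------------------------

small_config <- function(seed = 42, ...) {
  sim_config(n_terms = 60, n_genes = 60, n_modules = 6, terms_per_gene = 4,
             n_cell_lines = 10, mutations_per_cell = 2, n_drugs = 6,
             targets_per_drug = 2, seed = seed, ...)
}

fast_vgae <- function(seed = 1, epochs = 60, ...) {
  vgae_config(h0 = 16, h1 = 8, f = 8, epochs = epochs, patience = epochs,
              min_epochs = 1, seed = seed, ...)
}

# --- independent oracles -----------------------------------------------------

# entrywise normalized adjacency: Ahat[i,j] = Abar[i,j] / sqrt(dbar_i dbar_j)
brute_normalize <- function(A) {
  A <- as.matrix(A)
  n <- nrow(A)
  Abar <- A + diag(n)
  d <- rowSums(Abar)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- Abar[i, j] / sqrt(d[i] * d[j])
  out
}

# encoder evaluated entry by entry with scalar loops, no matrix primitives
brute_encode <- function(Ahat, X, params) {
  Ahat <- as.matrix(Ahat); X <- as.matrix(X)
  n <- nrow(X)
  f_in <- ncol(X); h0 <- ncol(params$W0); h1 <- ncol(params$W1)
  f <- ncol(params$W2)
  mm <- function(A, B) {
    out <- matrix(0, nrow(A), ncol(B))
    for (i in seq_len(nrow(A))) for (j in seq_len(ncol(B))) {
      acc <- 0
      for (k in seq_len(ncol(A))) acc <- acc + A[i, k] * B[k, j]
      out[i, j] <- acc
    }
    out
  }
  Xbar <- mm(X, params$W0)
  for (i in seq_len(n)) for (j in seq_len(h0))
    Xbar[i, j] <- Xbar[i, j] + params$b[j]
  S <- mm(mm(Ahat, Xbar), params$W1)
  Tt <- S
  if (params$sigma1 == "relu")
    for (i in seq_len(n)) for (j in seq_len(h1)) Tt[i, j] <- max(S[i, j], 0)
  AT <- mm(Ahat, Tt)
  list(mu = mm(AT, params$W2), logvar = mm(AT, params$W3))
}

# AUROC by exhaustive concordance over all positive-negative pairs
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  acc <- 0
  for (p in pos) for (q in neg)
    acc <- acc + (if (p > q) 1 else if (p == q) 0.5 else 0)
  acc / (length(pos) * length(neg))
}

# all symmetric binary adjacencies with zero diagonal on n nodes
all_adjacencies <- function(n) {
  m <- n * (n - 1) / 2
  lapply(seq_len(2^m) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(m)]
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- bits
    A + t(A)
  })
}

random_adjacency <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}
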