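# Internal helpers shared across modules.

#' @importFrom stats median quantile rbinom rnorm runif setNames
#' @importFrom utils head read.delim write.table
NULL

# Node identifiers are opaque case-sensitive strings; a type prefix is applied
# internally so that a gene, a cell line and a drug that happen to share a raw
# id can never collide in one adjacency.
ns_id <- function(id, type) {
  if (length(id) == 0L) return(character())
  prefix <- c(gene = "gene:", cell_line = "cell:", drug = "drug:")[type]
  paste0(prefix, id)
}

strip_ns <- function(id) sub("^(gene|cell|drug):", "", id)

ns_type <- function(id) {
  type <- c(gene = "gene", cell = "cell_line", drug = "drug")[sub(":.*$", "", id)]
  unname(type)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# log(1 + exp(x)) without overflow
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ol <- function(...) stop(..., call. = FALSE)

# Canonicalize an unordered pair: lexicographically smaller id first.
canonical_pair <- function(a, b) {
  swap <- b < a
  list(source = ifelse(swap, b, a), target = ifelse(swap, a, b))
}

pair_key <- function(a, b) paste(a, b, sep = "\r")
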