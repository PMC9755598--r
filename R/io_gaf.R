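#' Parse GO annotations from a GAF 2.x file
#'
#' Reads the 17-column tab-separated GAF dialect (comment lines start with
#' `!`). Gene identifiers are taken from column 3 (DB Object Symbol), terms
#' from column 5 (GO ID), evidence codes from column 7.
#'
#' Annotations whose evidence code is in `drop_evidence` are removed; the
#' default drops IGI ("inferred from genetic interaction") to avoid
#' circularity when the downstream task is genetic-interaction prediction.
#' Annotations pointing at terms absent from `dag` are skipped and counted.
#'
#' @param path path to a GAF file, or a character vector of its lines.
#' @param dag an [ontology_dag][parse_obo] restricting the valid terms.
#' @param drop_evidence character vector of evidence codes to remove.
#' @return an `annotation_set`: list with `direct` (named list mapping gene to
#'   a data.frame with columns `term`, `evidence`) and `n_skipped_terms`
#'   (count of rows referencing unknown terms).
#' @export
parse_annotations <- function(path, dag, drop_evidence = "IGI") {
  stopifnot(inherits(dag, "ontology_dag"))
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]

  if (length(lines) == 0L) {
    warning("empty annotation input: no genes annotated")
    return(new_annotation_set(list(), 0L))
  }

  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 7L)
  if (length(bad) > 0L)
    stop_ol("GAF row ", bad[[1L]], " has fewer than 7 columns")

  gene <- vapply(fields, `[[`, "", 3L)
  term <- vapply(fields, `[[`, "", 5L)
  evidence <- vapply(fields, `[[`, "", 7L)

  keep_ev <- !(evidence %in% drop_evidence)
  known <- term %in% dag$terms
  n_skipped <- sum(keep_ev & !known)
  keep <- keep_ev & known

  direct <- list()
  if (any(keep)) {
    df <- unique(data.frame(gene = gene[keep], term = term[keep],
                            evidence = evidence[keep], stringsAsFactors = FALSE))
    direct <- split(df[c("term", "evidence")], df$gene)
    direct <- lapply(direct, function(d) {
      rownames(d) <- NULL
      d[order(d$term, d$evidence), , drop = FALSE]
    })
  }
  if (length(direct) == 0L) warning("no annotations survived filtering")
  new_annotation_set(direct, n_skipped)
}

new_annotation_set <- function(direct, n_skipped = 0L) {
  structure(list(direct = direct, n_skipped_terms = as.integer(n_skipped)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set: ", length(x$direct), " genes, ",
      sum(vapply(x$direct, nrow, 0L)), " direct annotations",
      if (x$n_skipped_terms > 0L)
        paste0(" (", x$n_skipped_terms, " rows to unknown terms skipped)"),
      "\n", sep = "")
  invisible(x)
}

#' Direct term sets of an annotation set
#'
#' @param annots an `annotation_set`.
#' @return named list mapping gene id to a sorted character vector of
#'   directly annotated terms.
#' @export
direct_terms <- function(annots) {
  stopifnot(inherits(annots, "annotation_set"))
  lapply(annots$direct, function(d) sort(unique(d$term)))
}

#' Serialize an annotation set to GAF 2.2
#'
#' @param annots an `annotation_set`.
#' @param path output path, or `NULL` to only return the lines.
#' @param db database label for column 1.
#' @return the GAF lines, invisibly.
#' @export
write_gaf <- function(annots, path = NULL, db = "ONTOLINK") {
  stopifnot(inherits(annots, "annotation_set"))
  lines <- "!gaf-version: 2.2"
  for (g in names(annots$direct)) {
    d <- annots$direct[[g]]
    for (i in seq_len(nrow(d))) {
      row <- rep("", 17L)
      row[1] <- db; row[2] <- g; row[3] <- g; row[5] <- d$term[[i]]
      row[6] <- paste0(db, ":0000001"); row[7] <- d$evidence[[i]]
      row[9] <- "P"; row[12] <- "gene"; row[13] <- "taxon:0"
      row[14] <- "20220101"; row[15] <- db
      lines <- c(lines, paste(row, collapse = "\t"))
    }
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
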