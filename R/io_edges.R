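#' Filtering rules for reading edge tables
#'
#' Holds the thresholds that binarize raw interaction scores into
#' positive/neutral labels, mirroring the preprocessing applied to the real
#' data sources: genetic-interaction calls at a p-value cutoff plus a score
#' cutoff (e.g. p <= 0.05 and score <= -0.08 for negative GIs), gene
#' dependencies at a probability cutoff (0.5), and harmful-mutation classes
#' as an allow-list of variant-class strings.
#'
#' @param score_threshold numeric score cutoff, or `NULL`.
#' @param p_threshold numeric p-value cutoff (rows failing it are dropped),
#'   or `NULL`.
#' @param direction which side of `score_threshold` counts as positive:
#'   `"le"` (score <= cutoff; the convention for negative-GI scores) or
#'   `"ge"` (score >= cutoff; the convention for dependency probabilities).
#' @param variant_classes character allow-list of harmful variant classes for
#'   mutation tables, or `NULL` to accept every class.
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(score_threshold = NULL, p_threshold = NULL,
                        direction = c("le", "ge"), variant_classes = NULL) {
  direction <- match.arg(direction)
  structure(list(score_threshold = score_threshold, p_threshold = p_threshold,
                 direction = direction, variant_classes = variant_classes),
            class = "filter_spec")
}

EDGE_TYPES <- c("gi", "dependency", "mutation", "drug_target", "sensitivity")

edge_schema <- function(edge_type) {
  switch(edge_type,
    gi          = c("gene",      "gene"),
    dependency  = c("cell_line", "gene"),
    mutation    = c("cell_line", "gene"),
    drug_target = c("drug",      "gene"),
    sensitivity = c("drug",      "cell_line"),
    stop_ol("unknown edge_type: ", edge_type))
}

new_edge_table <- function(df, edge_type) {
  stopifnot(edge_type %in% EDGE_TYPES)
  for (col in c("score", "p_value"))
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  df <- df[c("source", "target", "label", "score", "p_value")]
  df <- df[order(df$source, df$target), , drop = FALSE]  # canonical row order
  rownames(df) <- NULL
  structure(df, edge_type = edge_type, class = c("edge_table", "data.frame"))
}

#' @export
print.edge_table <- function(x, ...) {
  cat("edge_table [", attr(x, "edge_type"), "]: ", nrow(x), " pairs (",
      sum(x$label == "positive"), " positive, ",
      sum(x$label == "neutral"), " neutral)\n", sep = "")
  if (nrow(x) > 0L) print.data.frame(head(as.data.frame(x), 5L))
  invisible(x)
}

#' Read a delimited edge table and binarize it
#'
#' Reads a tab-separated table with a header line. Required columns are
#' `source` and `target`; optional columns `score`, `p_value`, `label` and
#' (for mutation tables) `variant_class` are used by the filtering rules of
#' [filter_spec()].
#'
#' Labeling: if thresholds are supplied, rows failing the p-value cutoff are
#' dropped, and the score cutoff splits the survivors into positive and
#' neutral; if a `label` column is present and no thresholds are supplied,
#' labels pass through unchanged; otherwise every row is positive. Unordered
#' gene-gene (gi) pairs are canonicalized (lexicographically smaller id
#' first), self-pairs are dropped with a warning, and duplicate pairs are
#' collapsed keeping the row with the most extreme (largest magnitude) score.
#'
#' @param path path to a TSV file, or a data.frame already in memory.
#' @param edge_type one of `"gi"`, `"dependency"`, `"mutation"`,
#'   `"drug_target"`, `"sensitivity"`.
#' @param filters a [filter_spec()], or `NULL` for no thresholding.
#' @return an `edge_table` (data.frame with columns `source`, `target`,
#'   `label`, `score`, `p_value`; attribute `edge_type`).
#' @export
read_edge_table <- function(path, edge_type = EDGE_TYPES, filters = NULL) {
  edge_type <- match.arg(edge_type)
  df <- if (is.data.frame(path)) path
        else read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)

  required <- c("source", "target")
  if (!all(required %in% names(df)))
    stop_ol("edge table for type '", edge_type, "' must have columns ",
            "source, target (and optionally score, p_value, label",
            if (edge_type == "mutation") ", variant_class", "); got: ",
            paste(names(df), collapse = ", "))
  df$source <- as.character(df$source)
  df$target <- as.character(df$target)

  f <- filters %||% filter_spec()

  if (!is.null(f$p_threshold)) {
    if (is.null(df$p_value))
      stop_ol("p-value filtering requested but no p_value column present")
    df <- df[!is.na(df$p_value) & df$p_value <= f$p_threshold, , drop = FALSE]
  }

  if (!is.null(f$score_threshold)) {
    if (is.null(df$score))
      stop_ol("score filtering requested but no score column present")
    hit <- if (f$direction == "le") df$score <= f$score_threshold
           else df$score >= f$score_threshold
    df$label <- ifelse(!is.na(hit) & hit, "positive", "neutral")
  } else if (edge_type == "mutation" && !is.null(f$variant_classes)) {
    if (is.null(df$variant_class))
      stop_ol("variant-class filtering requested but no variant_class column")
    df$label <- ifelse(df$variant_class %in% f$variant_classes,
                       "positive", "neutral")
  } else if (is.null(df$label)) {
    df$label <- "positive"
  }
  df$label <- as.character(df$label)
  if (!all(df$label %in% c("positive", "neutral")))
    stop_ol("edge labels must be 'positive' or 'neutral'")

  if (edge_type == "gi") {
    self <- df$source == df$target
    if (any(self)) {
      warning(sum(self), " self-pair(s) dropped from gi table")
      df <- df[!self, , drop = FALSE]
    }
    cp <- canonical_pair(df$source, df$target)
    df$source <- cp$source; df$target <- cp$target
  }

  # collapse duplicate (ordered-canonical) pairs, keeping the most extreme score
  if (nrow(df) > 0L) {
    key <- pair_key(df$source, df$target)
    mag <- abs(df[["score"]] %||% rep(NA_real_, nrow(df)))
    mag[is.na(mag)] <- -Inf
    pos_first <- as.integer(df$label == "positive")  # tie-break: keep positive
    ord <- order(key, -mag, -pos_first)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(key[ord]), , drop = FALSE]
    df <- df[order(df$source, df$target), , drop = FALSE]
  }

  new_edge_table(df, edge_type)
}

#' Write an edge table as TSV
#'
#' The output re-reads through [read_edge_table()] with no filters to an
#' identical table (idempotence).
#'
#' @param et an `edge_table`.
#' @param path output path, or `NULL` to return the data.frame only.
#' @return the written data.frame, invisibly.
#' @export
write_edge_table <- function(et, path = NULL) {
  stopifnot(inherits(et, "edge_table"))
  out <- as.data.frame(et)
  for (col in c("p_value", "score"))
    if (all(is.na(out[[col]]))) out[[col]] <- NULL
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write link predictions as a ranked TSV
#'
#' @param pairs data.frame (or 2-column matrix) of `source`, `target` ids.
#' @param scores numeric vector of predicted probabilities, same length.
#' @param path output path, or `NULL` to return the table only.
#' @return the ordered data.frame, invisibly. Columns are `source`, `target`,
#'   `score` (printed with 6 decimal digits); rows are sorted by descending
#'   score, ties broken lexicographically by source then target id.
#' @export
write_predictions <- function(pairs, scores, path = NULL) {
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 2L) stop_ol("pairs must have two columns")
  names(pairs)[1:2] <- c("source", "target")
  if (nrow(pairs) != length(scores))
    stop_ol("pairs (", nrow(pairs), ") and scores (", length(scores),
            ") differ in length")
  out <- data.frame(source = as.character(pairs$source),
                    target = as.character(pairs$target),
                    score = sprintf("%.6f", scores),
                    stringsAsFactors = FALSE)
  out <- out[order(-as.numeric(out$score), out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read a prediction table written by [write_predictions()]
#'
#' @param path TSV path.
#' @return data.frame with columns `source`, `target`, `score` (numeric).
#' @export
read_predictions <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "character", "numeric"))
  df
}
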