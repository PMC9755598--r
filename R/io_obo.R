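#' Parse an OBO 1.2/1.4 ontology file into a term DAG
#'
#' Reads `[Term]` stanzas and records `is_a:` and `relationship: part_of`
#' links as parent links (the two are merged for ancestor traversal, the
#' convention of ontotype-style feature schemes). Obsolete terms are dropped,
#' together with any parent link pointing at them. All three Gene Ontology
#' namespaces (biological_process, cellular_component, molecular_function)
#' are retained.
#'
#' @param path path to an OBO file, or a character vector of its lines.
#' @return an object of class `ontology_dag`: a list with
#'   \describe{
#'     \item{terms}{character vector of retained term ids (sorted)}
#'     \item{parents}{named list mapping term id to character vector of
#'       parent term ids}
#'     \item{namespace}{named character vector mapping term id to namespace}
#'     \item{name}{named character vector of term names (may be `NA`)}
#'   }
#' @details Malformed stanza lines raise an error naming the offending line
#'   number; a parent reference to a term absent from the file raises an
#'   error listing the orphans; a cycle among parent links raises an error.
#' @export
parse_obo <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path

  term_ids <- character()
  parents <- list()
  namespace <- character()
  tname <- character()
  obsolete <- character()

  in_term <- FALSE
  cur_id <- NA_character_
  cur_parents <- character()
  cur_ns <- NA_character_
  cur_name <- NA_character_
  cur_obs <- FALSE

  flush_term <- function() {
    if (is.na(cur_id)) return(invisible())
    if (cur_obs) {
      obsolete <<- c(obsolete, cur_id)
    } else {
      term_ids <<- c(term_ids, cur_id)
      parents[[cur_id]] <<- unique(cur_parents)
      namespace[cur_id] <<- cur_ns
      tname[cur_id] <<- cur_name
    }
    invisible()
  }

  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (line == "" || startsWith(line, "!")) next
    if (startsWith(line, "[")) {
      if (in_term) flush_term()
      in_term <- identical(line, "[Term]")
      cur_id <- NA_character_; cur_parents <- character()
      cur_ns <- NA_character_; cur_name <- NA_character_; cur_obs <- FALSE
      next
    }
    if (!in_term) next
    colon <- regexpr(":", line, fixed = TRUE)
    if (colon < 1L)
      stop_ol("malformed OBO stanza line ", i, ": '", line, "'")
    key <- substr(line, 1L, colon - 1L)
    val <- trimws(substr(line, colon + 1L, nchar(line)))
    val <- sub("\\s*!.*$", "", val)  # trailing comment
    if (key == "id") {
      if (val == "") stop_ol("malformed OBO stanza line ", i, ": empty id")
      cur_id <- val
    } else if (key == "is_a") {
      cur_parents <- c(cur_parents, val)
    } else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (length(parts) >= 2L && parts[[1]] == "part_of")
        cur_parents <- c(cur_parents, parts[[2]])
    } else if (key == "namespace") {
      cur_ns <- val
    } else if (key == "name") {
      cur_name <- val
    } else if (key == "is_obsolete") {
      cur_obs <- identical(val, "true")
    }
  }
  if (in_term) flush_term()

  # links into obsolete terms are dropped with the term itself
  parents <- lapply(parents, setdiff, y = obsolete)

  known <- c(term_ids, obsolete)
  orphan <- setdiff(unique(unlist(parents, use.names = FALSE)), known)
  if (length(orphan) > 0L)
    stop_ol("OBO parent reference(s) to term(s) absent from file: ",
            paste(sort(orphan), collapse = ", "))

  dag <- new_ontology_dag(sort(term_ids), parents, namespace, tname)
  assert_acyclic(dag)
  dag
}

new_ontology_dag <- function(terms, parents, namespace, name = NULL) {
  parents <- parents[terms]
  names(parents) <- terms
  parents <- lapply(parents, function(p) if (is.null(p)) character() else p)
  structure(
    list(terms = terms, parents = parents,
         namespace = namespace[terms],
         name = (name %||% setNames(rep(NA_character_, length(terms)), terms))[terms]),
    class = "ontology_dag"
  )
}

# Depth-first search over parent links; raises on any directed cycle.
assert_acyclic <- function(dag) {
  state <- setNames(integer(length(dag$terms)), dag$terms)  # 0 new, 1 open, 2 done
  visit <- function(t) {
    if (state[[t]] == 2L) return(invisible())
    if (state[[t]] == 1L)
      stop_ol("cycle detected in ontology parent links at term ", t)
    state[[t]] <<- 1L
    for (p in dag$parents[[t]]) visit(p)
    state[[t]] <<- 2L
    invisible()
  }
  for (t in dag$terms) visit(t)
  invisible(dag)
}

#' @export
print.ontology_dag <- function(x, ...) {
  n_links <- sum(lengths(x$parents))
  cat("ontology_dag: ", length(x$terms), " terms, ", n_links,
      " parent links\n", sep = "")
  ns <- table(x$namespace)
  if (length(ns)) cat("  namespaces:",
                      paste(names(ns), ns, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a term DAG to OBO format
#'
#' Writes a minimal OBO 1.2 document that [parse_obo()] reads back to an
#' identical DAG (same terms, parent links and namespaces).
#'
#' @param dag an `ontology_dag`.
#' @param path output file path; if `NULL`, the lines are returned invisibly
#'   without writing.
#' @return the OBO lines, invisibly.
#' @export
write_obo <- function(dag, path = NULL) {
  stopifnot(inherits(dag, "ontology_dag"))
  lines <- c("format-version: 1.2", "")
  for (t in dag$terms) {
    lines <- c(lines, "[Term]", paste0("id: ", t))
    if (!is.na(dag$name[[t]])) lines <- c(lines, paste0("name: ", dag$name[[t]]))
    if (!is.na(dag$namespace[[t]]))
      lines <- c(lines, paste0("namespace: ", dag$namespace[[t]]))
    for (p in dag$parents[[t]]) lines <- c(lines, paste0("is_a: ", p))
    lines <- c(lines, "")
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
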