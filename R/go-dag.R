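#' Construct a GO DAG object
#'
#' A minimal ontology container: a term table and an `is_a` edge table.
#' Validated to be acyclic, with every parent present and namespaces drawn
#' from the three GO categories.
#'
#' @param terms Tibble with `term_id`, `name`, `namespace`.
#' @param parents Tibble with `term_id`, `parent_id` (`is_a` edges).
#' @return A list of class `go_dag` with `terms`, `parents` and an igraph
#'   `graph` (edges child -> parent).
#' @export
go_dag <- function(terms, parents) {
  ns_ok <- c("biological_process", "molecular_function", "cellular_component")
  if (!all(terms$namespace %in% ns_ok)) {
    stop("unknown namespace(s): ",
         paste(setdiff(unique(terms$namespace), ns_ok), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(parents$parent_id, terms$term_id)
  if (length(missing) > 0) {
    stop("parent id(s) absent from term table: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    parents[, c("term_id", "parent_id")], directed = TRUE,
    vertices = terms$term_id)
  if (!igraph::is_dag(g)) stop("ontology graph contains a cycle", call. = FALSE)
  structure(list(terms = tibble::as_tibble(terms),
                 parents = tibble::as_tibble(parents), graph = g),
            class = "go_dag")
}

#' Ancestors of ontology terms (is_a closure, term itself included)
#' @param dag A [go_dag()].
#' @param term_ids Character vector of term ids.
#' @return Named list: term id -> character vector of itself plus ancestors.
#' @export
go_ancestors <- function(dag, term_ids = dag$terms$term_id) {
  lapply(setNames(term_ids, term_ids), function(t) {
    names(igraph::subcomponent(dag$graph, t, mode = "out"))
  })
}

#' Read an OBO ontology file (subset: id, name, namespace, is_a)
#'
#' Relationship lines other than `is_a` (e.g. `relationship: part_of`) are
#' ignored with a warning; obsolete terms are dropped.
#' @param path OBO file path.
#' @return A [go_dag()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0) stop("no [Term] stanzas in ", path, call. = FALSE)
  bounds <- c(term_starts, length(lines) + 1L)
  terms <- list(); parents <- list(); saw_other_rel <- FALSE
  for (i in seq_along(term_starts)) {
    block <- lines[(bounds[i] + 1):(bounds[i + 1] - 1)]
    block <- block[!grepl("^\\[", block)]
    field <- function(key) {
      v <- block[startsWith(block, paste0(key, ": "))]
      sub(paste0("^", key, ": "), "", v)
    }
    if (length(field("is_obsolete")) > 0 && field("is_obsolete")[1] == "true") next
    id <- field("id")[1]
    if (is.na(id) || is.null(id)) next
    nm <- field("name"); ns <- field("namespace")
    terms[[i]] <- tibble(term_id = id,
                         name = if (length(nm)) nm[1] else id,
                         namespace = if (length(ns)) ns[1] else NA_character_)
    isa <- sub("\\s*!.*$", "", field("is_a"))
    if (length(isa) > 0) {
      parents[[i]] <- tibble(term_id = id, parent_id = isa)
    }
    if (any(startsWith(block, "relationship: "))) saw_other_rel <- TRUE
  }
  if (saw_other_rel) {
    warning("relationships other than is_a are ignored", call. = FALSE)
  }
  go_dag(dplyr::bind_rows(terms),
         dplyr::bind_rows(parents) %||%
           tibble(term_id = character(), parent_id = character()))
}

#' Write a GO DAG to OBO format
#' @param dag A [go_dag()].
#' @param path Output path.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(dag$terms))) {
    t <- dag$terms[i, ]
    isa <- dag$parents$parent_id[dag$parents$term_id == t$term_id]
    writeLines(c("[Term]",
                 paste0("id: ", t$term_id),
                 paste0("name: ", t$name),
                 paste0("namespace: ", t$namespace),
                 if (length(isa)) paste0("is_a: ", isa),
                 ""), con)
  }
  invisible(path)
}
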