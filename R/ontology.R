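#' Minimal ontology DAG
#'
#' Holds the term table and `is_a` parent lists of a Gene Ontology style
#' directed acyclic graph.  The dialect is deliberately minimal: only
#' `id`, `name`, `namespace`, `is_a` and `is_obsolete` are honored (no
#' `relationship:` edges, no cross-products).  Obsolete terms are kept in
#' the term table but excluded from traversal.
#'
#' @param terms `data.frame` with columns `id`, `name`, `namespace`,
#'   `obsolete`.
#' @param parents Named list mapping each term id to the character vector
#'   of its `is_a` parents.
#' @return An object of class `"ontology_dag"`.
#' @export
new_ontology_dag <- function(terms, parents) {
  stopifnot(all(c("id", "name", "namespace", "obsolete") %in% names(terms)))
  if (anyDuplicated(terms$id)) {
    stop("duplicate term id(s): ",
         paste(unique(terms$id[duplicated(terms$id)]), collapse = ", "),
         call. = FALSE)
  }
  missing_nodes <- setdiff(names(parents), terms$id)
  if (length(missing_nodes)) {
    stop("parents listed for unknown term(s): ",
         paste(missing_nodes, collapse = ", "), call. = FALSE)
  }
  endpoints <- setdiff(unique(unlist(parents, use.names = FALSE)), terms$id)
  if (length(endpoints)) {
    stop("is_a edge points at unknown term(s): ",
         paste(endpoints, collapse = ", "), call. = FALSE)
  }
  parents <- parents[terms$id]
  names(parents) <- terms$id
  parents <- lapply(parents, function(p) if (is.null(p)) character(0) else p)
  dag <- structure(list(terms = terms, parents = parents),
                   class = "ontology_dag")
  assert_acyclic(dag)
  dag
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("ontology_dag: %d terms (%d obsolete), %d is_a edges\n",
              nrow(x$terms), sum(x$terms$obsolete),
              length(unlist(x$parents, use.names = FALSE))))
  invisible(x)
}

# Depth-first three-color check; a back edge means a cyclic is_a chain.
assert_acyclic <- function(dag) {
  color <- new.env(parent = emptyenv())
  visit <- function(id) {
    state <- mget(id, envir = color, ifnotfound = "white")[[1]]
    if (state == "grey") stop("cyclic is_a chain involving ", id,
                              call. = FALSE)
    if (state == "black") return(invisible())
    assign(id, "grey", envir = color)
    for (p in dag$parents[[id]]) visit(p)
    assign(id, "black", envir = color)
  }
  for (id in dag$terms$id) visit(id)
  invisible(dag)
}

#' Read a minimal OBO 1.2 subset
#'
#' Parses `[Term]` stanzas honoring only `id:`, `name:`, `namespace:`,
#' `is_a:` (trailing `! comment` stripped) and `is_obsolete:`.  A cyclic
#' `is_a` chain is a hard error; obsolete terms are retained but excluded
#' from all traversal.
#'
#' @param path Path to an OBO file.
#' @return An [new_ontology_dag()] object.
#' @export
read_obo_subset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  starts <- which(lines == "[Term]")
  if (!length(starts)) stop("no [Term] stanzas in ", path, call. = FALSE)
  boundaries <- c(starts, length(lines) + 1L)
  recs <- lapply(seq_along(starts), function(i) {
    chunk <- lines[(boundaries[i] + 1L):(boundaries[i + 1L] - 1L)]
    chunk <- chunk[nzchar(chunk) & !startsWith(chunk, "[")]
    field <- function(key) {
      hits <- chunk[startsWith(chunk, paste0(key, ": "))]
      sub("\\s*!.*$", "", substring(hits, nchar(key) + 3L))
    }
    id <- field("id")
    if (length(id) != 1L) stop("stanza without a single id in ", path,
                               call. = FALSE)
    nm <- field("name")
    ns <- field("namespace")
    list(id = id,
         name = if (length(nm)) nm[1] else id,
         namespace = if (length(ns)) ns[1] else "biological_process",
         obsolete = any(tolower(field("is_obsolete")) == "true"),
         is_a = field("is_a"))
  })
  terms <- data.frame(
    id = vapply(recs, `[[`, "", "id"),
    name = vapply(recs, `[[`, "", "name"),
    namespace = vapply(recs, `[[`, "", "namespace"),
    obsolete = vapply(recs, `[[`, NA, "obsolete"),
    stringsAsFactors = FALSE)
  parents <- lapply(recs, `[[`, "is_a")
  names(parents) <- terms$id
  new_ontology_dag(terms, parents)
}

#' Write an ontology DAG back to the minimal OBO dialect
#'
#' @param dag An [new_ontology_dag()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo_subset <- function(dag, path) {
  stopifnot(inherits(dag, "ontology_dag"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(dag$terms))) {
    writeLines("", con)
    writeLines("[Term]", con)
    writeLines(paste0("id: ", dag$terms$id[i]), con)
    writeLines(paste0("name: ", dag$terms$name[i]), con)
    writeLines(paste0("namespace: ", dag$terms$namespace[i]), con)
    for (p in dag$parents[[dag$terms$id[i]]]) {
      writeLines(paste0("is_a: ", p), con)
    }
    if (dag$terms$obsolete[i]) writeLines("is_obsolete: true", con)
  }
  invisible(path)
}

#' All is_a ancestors of a term
#'
#' Breadth-first traversal over `is_a` parents, skipping obsolete terms
#' (they are neither returned nor traversed through).  The term itself is
#' not an ancestor of itself.
#'
#' @param dag An [new_ontology_dag()] object.
#' @param id Term id (must exist in the DAG and not be obsolete).
#' @return Character vector of ancestor ids (unordered, unique).
#' @export
term_ancestors <- function(dag, id) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!id %in% dag$terms$id) stop("unknown term id: ", id, call. = FALSE)
  obsolete <- dag$terms$id[dag$terms$obsolete]
  seen <- character(0)
  frontier <- setdiff(dag$parents[[id]], obsolete)
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier],
                                      use.names = FALSE)),
                        c(seen, obsolete))
  }
  unique(seen)
}

# Ancestor sets for many terms at once, as a named list (memoized by
# dynamic programming over a topological-ish recursion).
ancestor_closure <- function(dag, ids = NULL) {
  if (is.null(ids)) ids <- dag$terms$id[!dag$terms$obsolete]
  cache <- new.env(parent = emptyenv())
  obsolete <- dag$terms$id[dag$terms$obsolete]
  anc <- function(id) {
    if (!is.null(cache[[id]])) return(cache[[id]])
    ps <- setdiff(dag$parents[[id]], obsolete)
    out <- unique(c(ps, unlist(lapply(ps, anc), use.names = FALSE)))
    cache[[id]] <- out
    out
  }
  res <- lapply(ids, anc)
  names(res) <- ids
  res
}
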