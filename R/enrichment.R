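#' Propagate annotations up the ontology
#'
#' Under the true-path interpretation a gene annotated to a term is
#' implicitly annotated to every `is_a` ancestor of that term; this adds
#' those ancestor annotations explicitly.  Unknown term ids are an error
#' listing the offenders.
#'
#' @param ann An [annotation_set()].
#' @param dag An [new_ontology_dag()].
#' @return A new `annotation_set` with ancestor annotations added
#'   (idempotent).
#' @export
propagate_annotations <- function(ann, dag) {
  stopifnot(inherits(ann, "annotation_set"), inherits(dag, "ontology_dag"))
  unknown <- setdiff(unique(ann$pairs$term), dag$terms$id)
  if (length(unknown)) {
    stop("annotation(s) to unknown term(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  anc <- ancestor_closure(dag, unique(ann$pairs$term))
  extra <- lapply(seq_len(nrow(ann$pairs)), function(i) {
    up <- anc[[ann$pairs$term[i]]]
    if (!length(up)) return(NULL)
    data.frame(gene = ann$pairs$gene[i], term = up,
               stringsAsFactors = FALSE)
  })
  pairs <- rbind(ann$pairs, do.call(rbind, extra))
  annotation_set(pairs, ann$universe)
}

#' Hypergeometric term over-representation
#'
#' Tests, for every ontology term, whether the test gene set contains
#' more genes annotated to the term (directly or through ancestor
#' propagation) than expected from the background universe.  With N
#' universe genes, K annotated in the background, a test set of n and k
#' annotated test genes, the raw P value is the upper hypergeometric tail
#' `P(X >= k)`.  Terms are tested when at least one test gene (`k >= 1`)
#' and at least two background genes (`K >= 2`) carry them; the
#' Bonferroni multiplier is the number of tested terms and adjusted P
#' values are capped at 1.
#'
#' @param test_genes Character vector, a subset of the universe.
#' @param ann An [annotation_set()] (direct annotations).
#' @param dag An [new_ontology_dag()].
#' @param propagate Propagate annotations first (default TRUE).
#' @return `data.frame` of class `"enrichment_result"`: `term_id`,
#'   `term_name`, `k_test`, `K_background`, `n_test`, `N_background`,
#'   `p_raw`, `p_bonferroni`, sorted by `p_raw`.
#' @export
term_enrichment <- function(test_genes, ann, dag, propagate = TRUE) {
  stopifnot(inherits(ann, "annotation_set"), inherits(dag, "ontology_dag"))
  test_genes <- unique(as.character(test_genes))
  outside <- setdiff(test_genes, ann$universe)
  if (length(outside)) {
    stop("test gene(s) outside the background universe: ",
         paste(outside, collapse = ", "), call. = FALSE)
  }
  if (propagate) ann <- propagate_annotations(ann, dag)
  n_univ <- length(ann$universe)
  n_test <- length(test_genes)
  pairs <- ann$pairs
  k_bg <- table(pairs$term)
  k_test <- table(pairs$term[pairs$gene %in% test_genes])
  terms <- names(k_bg)[k_bg >= 2 & names(k_bg) %in% names(k_test)]
  k <- as.integer(k_test[terms])
  bigk <- as.integer(k_bg[terms])
  p_raw <- stats::phyper(k - 1L, bigk, n_univ - bigk, n_test,
                         lower.tail = FALSE)
  m <- length(terms)
  res <- data.frame(
    term_id = terms,
    term_name = dag$terms$name[match(terms, dag$terms$id)],
    k_test = k, K_background = bigk,
    n_test = n_test, N_background = n_univ,
    p_raw = p_raw,
    p_bonferroni = pmin(1, p_raw * m),
    stringsAsFactors = FALSE)
  res <- res[order(res$p_raw, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Filter enrichment results to significant annotations
#'
#' Keeps terms whose Bonferroni-adjusted P value is strictly below
#' `alpha` and which annotate at least `min_genes` test genes.
#'
#' @param results An enrichment result table.
#' @param alpha Bonferroni significance level (default 0.003).
#' @param min_genes Minimum annotated test genes (default 2).
#' @return The filtered table.
#' @export
select_significant <- function(results, alpha = 0.003, min_genes = 2L) {
  stop_if_not_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                            lower_open = TRUE, upper_open = TRUE)
  stop_if_not_scalar_number(min_genes, "min_genes", lower = 1)
  out <- results[results$p_bonferroni < alpha &
                   results$k_test >= min_genes, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remap a granular term onto a high-level slim set
#'
#' Returns the most specific slim ancestors of a term: slim terms
#' reachable through `is_a` with no other reachable slim term strictly
#' between.  A term already in the slim maps to itself; a term with no
#' slim ancestor maps to the empty set (reported, not an error).
#'
#' @param term_id Term id in the DAG.
#' @param dag An [new_ontology_dag()].
#' @param slim_terms Character vector of slim term ids (must exist in the
#'   DAG).
#' @return Character vector of slim term ids.
#' @export
slim_remap <- function(term_id, dag, slim_terms) {
  stopifnot(inherits(dag, "ontology_dag"))
  bad <- setdiff(slim_terms, dag$terms$id)
  if (length(bad)) {
    stop("slim term(s) not in the ontology: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (term_id %in% slim_terms) return(term_id)
  anc <- term_ancestors(dag, term_id)
  hits <- intersect(anc, slim_terms)
  if (length(hits) <= 1L) return(hits)
  anc_of <- ancestor_closure(dag, hits)
  # drop any slim hit that is an ancestor of another slim hit
  keep <- vapply(hits, function(s) {
    !any(vapply(setdiff(hits, s),
                function(other) s %in% anc_of[[other]], logical(1)))
  }, logical(1))
  hits[keep]
}

#' Collapse enriched terms into a final pathway report
#'
#' Applies the report-stage rules: blacklisted (nonspecific) terms are
#' removed; each term is assigned to the slim group(s) of its most
#' specific slim ancestors; groups sharing fewer than `min_report_genes`
#' distinct test genes are dropped; and within a slim group, a term whose
#' annotated test-gene set is a subset of another term's set is collapsed
#' into that superset term (ties between equal sets keep the term with
#' more background annotations, then the lexically smaller id).
#'
#' @param results Enrichment table (already filtered by
#'   [select_significant()]) carrying `term_id`, `term_name`,
#'   `K_background`, `p_raw`, `p_bonferroni`.
#' @param dag An [new_ontology_dag()].
#' @param ann The (propagated or direct) [annotation_set()] used to pull
#'   per-term test-gene memberships.
#' @param test_genes The test gene set.
#' @param slim_terms Slim term ids.
#' @param min_report_genes Minimum distinct genes per reported group
#'   (default 3).
#' @param blacklist Character vector of term ids or names to exclude as
#'   nonspecific; defaults to the packaged list.
#' @return `data.frame`: `term_id`, `term_name`, `slim_group`, `genes`
#'   (comma-separated, alphabetical), `n_genes`, `p_raw`, `p_bonferroni`,
#'   `absorbed` (ids collapsed into this term).
#' @export
collapse_and_report <- function(results, dag, ann, test_genes, slim_terms,
                                min_report_genes = 3L,
                                blacklist = default_blacklist()) {
  stop_if_not_scalar_number(min_report_genes, "min_report_genes", lower = 1)
  ann <- propagate_annotations(ann, dag)
  res <- results[!(results$term_id %in% blacklist |
                     results$term_name %in% blacklist), , drop = FALSE]
  if (!nrow(res)) return(empty_report())
  gene_sets <- lapply(res$term_id, function(t) {
    sort(intersect(ann$pairs$gene[ann$pairs$term == t], test_genes))
  })
  names(gene_sets) <- res$term_id
  groups <- lapply(res$term_id, slim_remap, dag = dag,
                   slim_terms = slim_terms)
  membership <- data.frame(
    term_id = rep(res$term_id, vapply(groups, length, 0L) +
                    (vapply(groups, length, 0L) == 0L)),
    slim_group = unlist(lapply(seq_along(groups), function(i) {
      if (length(groups[[i]])) groups[[i]] else
        paste0("unmapped:", res$term_id[i])
    })), stringsAsFactors = FALSE)
  reported <- lapply(unique(membership$slim_group), function(g) {
    ids <- membership$term_id[membership$slim_group == g]
    if (length(unique(unlist(gene_sets[ids]))) < min_report_genes) {
      return(NULL)
    }
    sub <- res[match(ids, res$term_id), , drop = FALSE]
    ord <- order(-vapply(gene_sets[ids], length, 0L), -sub$K_background,
                 ids)
    kept <- list()
    for (i in ord) {
      id <- ids[i]
      host <- NULL
      for (kid in names(kept)) {
        if (all(gene_sets[[id]] %in% gene_sets[[kid]])) {
          host <- kid
          break
        }
      }
      if (is.null(host)) kept[[id]] <- character(0) else
        kept[[host]] <- c(kept[[host]], id)
    }
    rows <- lapply(names(kept), function(id) {
      r <- res[res$term_id == id, , drop = FALSE]
      data.frame(term_id = id, term_name = r$term_name, slim_group = g,
                 genes = paste(gene_sets[[id]], collapse = ","),
                 n_genes = length(gene_sets[[id]]),
                 p_raw = r$p_raw, p_bonferroni = r$p_bonferroni,
                 absorbed = paste(kept[[id]], collapse = ","),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, reported)
  if (is.null(out)) return(empty_report())
  out <- out[order(out$p_raw, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_report <- function() {
  data.frame(term_id = character(0), term_name = character(0),
             slim_group = character(0), genes = character(0),
             n_genes = integer(0), p_raw = numeric(0),
             p_bonferroni = numeric(0), absorbed = character(0),
             stringsAsFactors = FALSE)
}

#' Default nonspecific-term blacklist
#'
#' High-level housekeeping terms excluded from the final pathway report
#' because they carry no pathway-level information (e.g. "biological
#' regulation").  Matched against term ids and names.
#'
#' @return Character vector.
#' @export
default_blacklist <- function() {
  c("biological_process", "biological regulation", "metabolic process",
    "cellular process", "response to stimulus")
}
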