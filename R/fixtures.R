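# Packaged fixtures: the published top-gene table and shared-pathway
# gene lists, transcribed verbatim, plus a synthetic annotation universe
# (synthetic_* files) sized so the pathway report is reproducible by the
# real enrichment code path with no external downloads.

fixture_checksums <- c(
  "top_genes_table.tsv"        = "52f6277f25fa14936d4687eaf819c17b",
  "pathway_terms.tsv"          = "0305b0f92c4986e5b90de52863a773db",
  "synthetic_go_subset.obo"    = "8364708273afe931b185fac154439161",
  "synthetic_annotations.tsv"  = "6e33bcc7789c632f2d7c019ab86bfdfa",
  "slim_terms.txt"             = "04e6b6d0f5050f03836514ed92406ef0",
  "nonspecific_terms.txt"      = "41290368d44e829316355a2d7e37c132"
)

fixture_path <- function(name, check = TRUE) {
  path <- system.file("extdata", name, package = "credmeta",
                      mustWork = TRUE)
  if (check) {
    got <- unname(tools::md5sum(path))
    if (!identical(got, unname(fixture_checksums[[name]]))) {
      stop("fixture checksum mismatch for ", name,
           " (file corrupted or modified)", call. = FALSE)
    }
  }
  path
}

#' Load the packaged published fixtures
#'
#' Returns the transcription of the published top-gene table (15
#' credibility-graded loci with chromosome, N minor, three-letter quality
#' string and per-stratum ORs with 95\% CIs) and the nine printed shared
#' pathway term-to-gene lists.  Both are verified against stored
#' checksums; a mismatch is a hard error.
#'
#' Two typographical inconsistencies of the source are stored as printed
#' and flagged in the `discrepancy` column rather than resolved: the LDLR
#' row's CI upper bound (0.89 in the table, 0.99 in the accompanying
#' text, kept in `ci_hi_alt`) and the TNF all-groups CI whose printed
#' lower bound exceeds the OR.
#'
#' @return List with `top_genes` (`data.frame`, 15 rows) and `pathways`
#'   (`data.frame`: `term_id`, `term_name`, `genes` semicolon-separated).
#' @export
load_paper_fixtures <- function() {
  top <- utils::read.delim(fixture_path("top_genes_table.tsv"),
                           stringsAsFactors = FALSE)
  pw <- utils::read.delim(fixture_path("pathway_terms.tsv"),
                          stringsAsFactors = FALSE)
  list(top_genes = top, pathways = pw)
}

#' Load the packaged synthetic enrichment inputs
#'
#' The ontology subset, gene annotations, slim list and nonspecific-term
#' blacklist that stand in for the historical GO/UniProtKB background the
#' original analysis queried (which is external and unarchived).  The
#' universe holds 1,000 synthetic background genes plus the 15 top genes.
#'
#' @return List with `dag`, `annotations`, `slim`, `blacklist`.
#' @export
load_fixture_universe <- function() {
  dag <- read_obo_subset(fixture_path("synthetic_go_subset.obo"))
  ann <- read_annotations(fixture_path("synthetic_annotations.tsv"))
  slim <- readLines(fixture_path("slim_terms.txt"), warn = FALSE)
  blacklist <- readLines(fixture_path("nonspecific_terms.txt"),
                         warn = FALSE)
  list(dag = dag, annotations = ann, slim = slim, blacklist = blacklist)
}

#' Run the pathway stage in fixture mode
#'
#' Executes the full over-representation path — ancestor propagation,
#' hypergeometric testing, Bonferroni selection, slim remapping,
#' blacklist and collapse — with the packaged synthetic universe, using
#' the 15 top genes as the test set.
#'
#' @param alpha,min_genes,min_report_genes Stage thresholds (defaults
#'   0.003, 2 and 3).
#' @return The final pathway report of [collapse_and_report()].
#' @export
run_fixture_enrichment <- function(alpha = 0.003, min_genes = 2L,
                                   min_report_genes = 3L) {
  fx <- load_paper_fixtures()
  uni <- load_fixture_universe()
  test_genes <- fx$top_genes$gene
  enr <- term_enrichment(test_genes, uni$annotations, uni$dag)
  sel <- select_significant(enr, alpha = alpha, min_genes = min_genes)
  collapse_and_report(sel, uni$dag, uni$annotations, test_genes,
                      uni$slim, min_report_genes = min_report_genes,
                      blacklist = uni$blacklist)
}

#' Copy the packaged fixtures to a directory
#'
#' @param dir Target directory (created if needed).
#' @return Invisibly, the copied paths.
#' @export
export_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(fixture_checksums), fixture_path, "")
  ok <- file.copy(paths, dir, overwrite = TRUE)
  if (!all(ok)) stop("failed to copy fixture file(s)", call. = FALSE)
  invisible(file.path(dir, names(fixture_checksums)))
}
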