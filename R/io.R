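#' Controlled vocabulary of population labels
#'
#' The closed set of population strata used throughout the pipeline.
#' Unknown labels encountered on input are mapped to `"other"` with a
#' warning.
#'
#' @return Character vector of allowed labels.
#' @export
population_levels <- function() {
  c("Caucasian", "Asian", "African", "Hispanic", "mixed", "other")
}

study_allele_cols <- c("case_minor", "case_major",
                       "control_minor", "control_major")
study_genotype_cols <- c("case_hom_minor", "case_het", "case_hom_major",
                         "control_hom_minor", "control_het",
                         "control_hom_major")
study_required_cols <- c("gene", "snp", "study_id", "population", "year",
                         study_allele_cols)

#' Validate a study table
#'
#' Checks column presence, non-negative counts, the controlled population
#' vocabulary, and — when the genotype block is present — consistency of
#' allele counts with genotype counts (minor = 2 x hom_minor + het).
#' Violations of the count invariants are reported with the offending row
#' numbers.
#'
#' @param studies A `data.frame` of per-study counts.
#' @return The validated (possibly population-recoded) table, invisibly
#'   classed as before.
#' @export
validate_study_table <- function(studies) {
  missing <- setdiff(study_required_cols, names(studies))
  if (length(missing)) {
    stop("study table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  has_geno <- all(study_genotype_cols %in% names(studies))
  count_cols <- c(study_allele_cols, if (has_geno) study_genotype_cols)
  for (col in count_cols) {
    v <- studies[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0)) {
      stop(sprintf("column '%s' must hold non-negative counts", col),
           call. = FALSE)
    }
  }
  unknown <- !(studies$population %in% population_levels())
  if (any(unknown)) {
    warning("unknown population label(s) ",
            paste(unique(studies$population[unknown]), collapse = ", "),
            " mapped to 'other'", call. = FALSE)
    studies$population[unknown] <- "other"
  }
  if (has_geno) {
    bad_case <- studies$case_minor !=
      2 * studies$case_hom_minor + studies$case_het
    bad_ctrl <- studies$control_minor !=
      2 * studies$control_hom_minor + studies$control_het
    bad_case2 <- studies$case_major !=
      2 * studies$case_hom_major + studies$case_het
    bad_ctrl2 <- studies$control_major !=
      2 * studies$control_hom_major + studies$control_het
    bad <- which(bad_case | bad_ctrl | bad_case2 | bad_ctrl2)
    if (length(bad)) {
      stop("allele counts inconsistent with genotype counts in row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(studies)
}

#' Read a per-study association count table
#'
#' Reads the tab-separated study table dialect used by the pipeline.  The
#' header must contain `gene, snp, study_id, population, year,
#' case_minor, case_major, control_minor, control_major`, optionally
#' followed by the six genotype columns `case_hom_minor, case_het,
#' case_hom_major, control_hom_minor, control_het, control_hom_major`.
#' When both blocks are present they must agree; inconsistencies are an
#' error naming the offending rows, never a silent preference.
#'
#' @param path Path to a TSV file.
#' @return A validated study `data.frame`.
#' @seealso [write_study_table()], [validate_study_table()]
#' @export
read_study_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  studies <- utils::read.delim(path, stringsAsFactors = FALSE,
                               check.names = FALSE)
  validate_study_table(studies)
  studies
}

#' Write a study table
#'
#' @param studies A study `data.frame` (validated before writing).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(studies, path) {
  validate_study_table(studies)
  utils::write.table(studies, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Gene-to-term annotation sets
#'
#' An annotation set pairs a gene/term mapping with the background
#' universe of genes against which over-representation is judged.  By
#' default the universe is all genes appearing in the mapping.
#'
#' @param pairs `data.frame` with columns `gene` and `term`.
#' @param universe Character vector of background gene ids; every
#'   annotated gene must belong to it.
#' @return An object of class `"annotation_set"`.
#' @export
annotation_set <- function(pairs, universe = NULL) {
  if (!all(c("gene", "term") %in% names(pairs))) {
    stop("'pairs' needs columns 'gene' and 'term'", call. = FALSE)
  }
  pairs <- unique(pairs[, c("gene", "term")])
  pairs <- pairs[order(pairs$gene, pairs$term), , drop = FALSE]
  rownames(pairs) <- NULL
  if (is.null(universe)) universe <- unique(pairs$gene)
  outside <- setdiff(pairs$gene, universe)
  if (length(outside)) {
    stop("annotated gene(s) outside the background universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(pairs = pairs, universe = sort(unique(universe))),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d annotations, %d genes annotated, %d in universe\n",
              nrow(x$pairs), length(unique(x$pairs$gene)),
              length(x$universe)))
  invisible(x)
}

#' Read gene annotations from 2-column TSV or a GAF subset
#'
#' Plain files are read as 2 columns (gene, term id), with or without a
#' header.  Files whose first data line has 15 or more tab-separated
#' fields are treated as GAF 2.x and columns 3 (object symbol) and 5
#' (term id) are used; all other GAF columns and `!` comment lines are
#' ignored.
#'
#' @param path Input path.
#' @param universe Optional explicit background universe; defaults to all
#'   genes in the file.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!")]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no annotation records in ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields[[1]]) >= 15L) {
    pairs <- data.frame(gene = vapply(fields, `[`, "", 3L),
                        term = vapply(fields, `[`, "", 5L),
                        stringsAsFactors = FALSE)
  } else {
    if (identical(tolower(fields[[1]][1:2]), c("gene", "term"))) {
      fields <- fields[-1L]
    }
    pairs <- data.frame(gene = vapply(fields, `[`, "", 1L),
                        term = vapply(fields, `[`, "", 2L),
                        stringsAsFactors = FALSE)
  }
  annotation_set(pairs, universe)
}

#' Write an annotation set as 2-column TSV
#'
#' @param ann An [annotation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  utils::write.table(ann$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("gene", "term"))
  invisible(path)
}
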