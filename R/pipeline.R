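#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline: input/output paths,
#' eligibility and grading thresholds, enrichment knobs, stage toggles
#' and the seed.  Defaults mirror the published procedure: control MAF
#' > 1\%, at least 4 independent samples, Bonferroni alpha 0.003 with at
#' least 2 genes at the enrichment stage, and at least 3 genes per
#' reported pathway group.
#'
#' @param study_file Path to a study TSV, or `NULL` to simulate.
#' @param annotations_file,obo_file,slim_file,blacklist_file Enrichment
#'   inputs; all `NULL` means use the packaged synthetic universe.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param maf_min,min_studies Eligibility thresholds.
#' @param hwe_alpha,asymmetry_alpha,pub_bias_test,pub_bias_policy Bias
#'   assessment knobs (see [assess_bias()]).
#' @param low_or_threshold,low_or_policy Low-OR criterion knobs.
#' @param alpha,min_genes,min_report_genes Enrichment-stage and
#'   report-stage thresholds.
#' @param do_grade,do_enrich Stage toggles.
#' @param sim When simulating, a [simulation_config()]-style list applied
#'   per gene, plus `n_genes` and `frac_null` (fraction of genes
#'   simulated with OR 1).
#' @param seed Integer master seed.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(study_file = NULL, annotations_file = NULL,
                            obo_file = NULL, slim_file = NULL,
                            blacklist_file = NULL, out_dir = NULL,
                            maf_min = 0.01, min_studies = 4L,
                            hwe_alpha = 0.05, asymmetry_alpha = 0.10,
                            pub_bias_test = "harbord",
                            pub_bias_policy = "corroborated",
                            low_or_threshold = 1.15,
                            low_or_policy = "corroborated",
                            alpha = 0.003, min_genes = 2L,
                            min_report_genes = 3L,
                            do_grade = TRUE, do_enrich = TRUE,
                            sim = list(n_genes = 5L, frac_null = 0.4,
                                       true_or = 1.4, tau2 = 0.005,
                                       k_studies = 6L, n_cases = 800L,
                                       n_controls = 800L,
                                       control_maf = 0.3),
                            seed = 1L) {
  stop_if_not_scalar_number(maf_min, "maf_min", lower = 0, upper = 0.5)
  stop_if_not_scalar_number(min_studies, "min_studies", lower = 1)
  stop_if_not_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                            lower_open = TRUE, upper_open = TRUE)
  structure(as.list(environment()), class = "pipeline_config")
}

format_or_ci <- function(or, lo, hi) {
  ifelse(is.na(or), "n.a", sprintf("%.2f (%.2f-%.2f)", or, lo, hi))
}

#' Grade an evidence base into a ranked top-gene list
#'
#' Runs eligibility filtering, minor-allele orientation, per-SNP
#' stratified random-effects meta-analysis, best-SNP selection per gene,
#' three-axis credibility grading and ranking.
#'
#' @param studies A validated study table (any number of genes/SNPs).
#' @param config A [pipeline_config()].
#' @return List with `meta` (stratified results for every eligible SNP),
#'   `top` (ranked graded gene table) and `eligible_snps`.
#' @export
grade_top_genes <- function(studies, config = pipeline_config()) {
  studies <- validate_study_table(studies)
  eligible <- eligibility_filter(studies, config$maf_min,
                                 config$min_studies)
  meta_rows <- list()
  per_snp_studies <- list()
  for (s in eligible) {
    sub <- orient_minor_allele(studies[studies$snp == s, , drop = FALSE])
    per_snp_studies[[s]] <- sub
    res <- stratified_meta(sub)
    res <- cbind(gene = sub$gene[1], snp = s, res,
                 stringsAsFactors = FALSE)
    meta_rows[[s]] <- res
  }
  meta <- if (length(meta_rows)) do.call(rbind, meta_rows) else NULL
  top <- NULL
  if (!is.null(meta) && isTRUE(config$do_grade)) {
    genes <- unique(meta$gene)
    rows <- lapply(genes, function(g) {
      gres <- meta[meta$gene == g, , drop = FALSE]
      best <- select_best_snp(gres)
      if (is.null(best)) return(NULL)
      all_row <- gres[gres$snp == best & gres$stratum == "all", ,
                      drop = FALSE]
      bias <- assess_bias(per_snp_studies[[best]],
                          low_or_threshold = config$low_or_threshold,
                          low_or_policy = config$low_or_policy,
                          hwe_alpha = config$hwe_alpha,
                          asymmetry_alpha = config$asymmetry_alpha,
                          pub_bias_test = config$pub_bias_test,
                          pub_bias_policy = config$pub_bias_policy)
      grades <- overall_credibility(amount_grade(all_row$n_minor),
                                    consistency_grade(all_row$i2),
                                    bias$grade)
      data.frame(gene = g, snp = best, n_minor = all_row$n_minor,
                 grades, or = all_row$or, ci_low = all_row$ci_low,
                 ci_high = all_row$ci_high, p = all_row$p,
                 i2 = all_row$i2, k = all_row$k,
                 stringsAsFactors = FALSE)
    })
    rows <- Filter(Negate(is.null), rows)
    if (length(rows)) top <- rank_top_list(do.call(rbind, rows))
  }
  list(meta = meta, top = top, eligible_snps = eligible)
}

#' Format the ranked top list in the published table layout
#'
#' One row per gene with N minor, the quality string and per-stratum
#' "OR (95\% CI)" strings; strata with fewer than two studies print
#' "n.a".
#'
#' @param graded Output of [grade_top_genes()].
#' @return A `data.frame` ready for TSV export.
#' @export
format_top_list <- function(graded) {
  if (is.null(graded$top)) return(NULL)
  meta <- graded$meta
  strata <- setdiff(unique(meta$stratum), "all")
  out <- graded$top[, c("gene", "snp", "n_minor", "quality_string",
                        "overall", "p")]
  for (s in c(strata, "all")) {
    vals <- vapply(seq_len(nrow(out)), function(i) {
      row <- meta[meta$snp == out$snp[i] & meta$stratum == s, ,
                  drop = FALSE]
      if (!nrow(row)) return("n.a")
      format_or_ci(row$or, row$ci_low, row$ci_high)
    }, "")
    out[[paste0(gsub(" ", "_", s), "_or_ci")]] <- vals
  }
  out
}

#' Run the full pipeline
#'
#' Executes (optional) simulation, eligibility + meta-analysis, grading
#' and ranking, and the pathway stage, writing one TSV per stage and a
#' machine-readable JSON run report when `out_dir` is set.  Every output
#' is deterministic given the config and seed, and the report carries the
#' config hash.
#'
#' @param config A [pipeline_config()].
#' @return List with `studies`, `graded`, `top_table`, `enrichment`,
#'   `report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  timings <- list()
  tick <- function(name, expr) {
    t <- Sys.time()
    out <- force(expr)
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t, units = "secs"))
    out
  }
  studies <- tick("input", {
    if (!is.null(config$study_file)) {
      read_study_table(config$study_file)
    } else {
      sim <- config$sim
      n_genes <- sim$n_genes %||% 5L
      frac_null <- sim$frac_null %||% 0.4
      n_null <- round(n_genes * frac_null)
      do.call(rbind, lapply(seq_len(n_genes), function(i) {
        cfg <- simulation_config(
          true_or = if (i <= n_null) 1 else sim$true_or %||% 1.4,
          tau2 = sim$tau2 %||% 0.02,
          k_studies = sim$k_studies %||% 6L,
          n_cases = sim$n_cases %||% 800L,
          n_controls = sim$n_controls %||% 800L,
          control_maf = sim$control_maf %||% 0.3,
          gene = sprintf("SIMG%02d", i),
          snp = sprintf("rs%07d", 1000000L + i),
          seed = config$seed + i)
        simulate_gene_studies(cfg)
      }))
    }
  })
  graded <- tick("meta_grade", grade_top_genes(studies, config))
  top_table <- format_top_list(graded)
  enrichment <- NULL
  if (isTRUE(config$do_enrich) && !is.null(graded$top)) {
    enrichment <- tick("enrich", {
      test_genes <- graded$top$gene[graded$top$overall %in% c("A", "B")]
      if (length(test_genes) >= 2) {
        inputs <- if (is.null(config$annotations_file)) {
          load_fixture_universe()
        } else {
          list(dag = read_obo_subset(config$obo_file),
               annotations = read_annotations(config$annotations_file),
               slim = readLines(config$slim_file, warn = FALSE),
               blacklist = if (is.null(config$blacklist_file))
                 default_blacklist() else
                   readLines(config$blacklist_file, warn = FALSE))
        }
        test_genes <- intersect(test_genes, inputs$annotations$universe)
        if (length(test_genes) >= 2) {
          enr <- term_enrichment(test_genes, inputs$annotations,
                                 inputs$dag)
          sel <- select_significant(enr, config$alpha, config$min_genes)
          list(all_terms = enr,
               report = collapse_and_report(
                 sel, inputs$dag, inputs$annotations, test_genes,
                 inputs$slim, config$min_report_genes, inputs$blacklist))
        } else NULL
      } else NULL
    })
  }
  hashable <- unclass(config)
  hashable$out_dir <- NULL
  report <- list(
    config_hash = object_md5(hashable),
    seed = config$seed,
    timings_sec = timings,
    counts = list(
      studies = nrow(studies),
      snps_total = length(unique(studies$snp)),
      snps_eligible = length(graded$eligible_snps),
      genes_graded = if (is.null(graded$top)) 0L else nrow(graded$top),
      genes_grade_a = if (is.null(graded$top)) 0L else
        sum(graded$top$overall == "A"),
      genes_grade_b = if (is.null(graded$top)) 0L else
        sum(graded$top$overall == "B"),
      terms_reported = if (is.null(enrichment)) 0L else
        nrow(enrichment$report)),
    total_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- function(df, name) {
      path <- file.path(config$out_dir, name)
      con <- file(path, "w")
      writeLines(paste0("# config_hash: ", report$config_hash), con)
      utils::write.table(df, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      close(con)
    }
    write_study_table(studies, file.path(config$out_dir, "studies.tsv"))
    if (!is.null(graded$meta)) stamp(graded$meta, "meta_results.tsv")
    if (!is.null(top_table)) stamp(top_table, "top_list.tsv")
    if (!is.null(enrichment)) {
      stamp(enrichment$all_terms, "enrichment_all_terms.tsv")
      stamp(enrichment$report, "pathway_report.tsv")
    }
    jsonlite::write_json(report,
                         file.path(config$out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(studies = studies, graded = graded, top_table = top_table,
       enrichment = enrichment, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
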