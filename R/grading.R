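#' Amount-of-evidence grade
#'
#' Grades the amount of evidence by the total number of minor alleles of
#' cases and controls combined in the meta-analysis ("N minor"): grade A
#' when N minor exceeds 1,000; grade B between 100 and 1,000 (both ends
#' inclusive); grade C below 100.
#'
#' @param n_minor Non-negative integer vector.
#' @return Character vector of grades ("A", "B" or "C").
#' @examples
#' amount_grade(c(4167, 227, 99, 1000))
#' @export
amount_grade <- function(n_minor) {
  if (any(n_minor < 0, na.rm = TRUE)) {
    stop("n_minor must be non-negative", call. = FALSE)
  }
  ifelse(n_minor > 1000, "A", ifelse(n_minor >= 100, "B", "C"))
}

#' Consistency-of-replication grade
#'
#' Grades consistency by the I-squared heterogeneity point estimate:
#' grade A below 25\%, grade B from 25\% to 50\% (inclusive), grade C
#' above 50\%.
#'
#' @param i2 I-squared percentages in [0, 100].
#' @return Character vector of grades.
#' @export
consistency_grade <- function(i2) {
  if (any(i2 < 0 | i2 > 100, na.rm = TRUE)) {
    stop("i2 must be a percentage in [0, 100]", call. = FALSE)
  }
  ifelse(i2 < 25, "A", ifelse(i2 <= 50, "B", "C"))
}

#' Egger's regression test for small-study effects
#'
#' Regresses the standard normal deviate of each study effect on its
#' precision; a non-zero intercept indicates funnel-plot asymmetry
#' consistent with publication bias.  The intercept is tested with a
#' two-sided t-test on k - 2 degrees of freedom; at least 3 studies are
#' required.
#'
#' @param log_or,var_log_or Study effects and sampling variances.
#' @return List with `intercept` and `p_value`.
#' @export
egger_test <- function(log_or, var_log_or) {
  k <- length(log_or)
  if (k < 3L) stop("Egger's test needs at least 3 studies", call. = FALSE)
  se <- sqrt(var_log_or)
  fit <- stats::lm(I(log_or / se) ~ I(1 / se))
  # duplicated study rows make the fit exact; the t-test is still defined
  cf <- suppressWarnings(summary(fit)$coefficients)
  list(intercept = unname(cf[1, 1]), p_value = unname(cf[1, 4]))
}

#' Harbord's score-based test for small-study effects in 2x2 tables
#'
#' Funnel-plot asymmetry test designed for odds ratios: regresses
#' `Z/sqrt(V)` on `sqrt(V)`, where Z is the score of the conditional
#' likelihood of each 2x2 allele table (`a - E[a]`) and V its Fisher
#' information.  Unlike Egger's regression on the log OR — whose standard
#' error is a function of the estimate itself, inflating the false-alarm
#' rate badly for effects away from OR 1 — the score and its information
#' are uncoupled, so the test holds its nominal level for the allele
#' contrasts pooled here.  Two-sided t-test on k - 2 df; k >= 3 required.
#'
#' @param case_minor,case_major,control_minor,control_major Allele
#'   counts per study.
#' @return List with `intercept` and `p_value`.
#' @export
harbord_test <- function(case_minor, case_major, control_minor,
                         control_major) {
  a <- as.numeric(case_minor); b <- as.numeric(case_major)
  c_ <- as.numeric(control_minor); d <- as.numeric(control_major)
  if (length(a) < 3L) {
    stop("Harbord's test needs at least 3 studies", call. = FALSE)
  }
  n <- a + b + c_ + d
  z <- a - (a + b) * (a + c_) / n
  v <- (a + b) * (c_ + d) * (a + c_) * (b + d) / (n^2 * (n - 1))
  fit <- stats::lm(I(z / sqrt(v)) ~ I(sqrt(v)))
  cf <- suppressWarnings(summary(fit)$coefficients)
  list(intercept = unname(cf[1, 1]), p_value = unname(cf[1, 4]))
}

#' Protection-from-bias assessment
#'
#' Evaluates the four potential reasons for bias in a pooled association:
#' a small summary effect (symmetric low-OR criterion
#' `max(OR, 1/OR) < low_or_threshold`), loss of significance after
#' excluding the first (earliest-year) study, loss of significance after
#' excluding studies whose control genotypes deviate from HWE (exact test
#' P < `hwe_alpha`), and evidence for publication bias.  Significance
#' always means the 95\% CI excluding OR = 1, and every re-pooling is the
#' full [pool_dersimonian_laird()] computation on the reduced study set
#' (a single remaining study falls back to its own Wald CI).
#'
#' Publication bias is screened by a funnel-asymmetry test
#' ([harbord_test()] by default, valid for odds ratios; Egger's
#' regression available) at `asymmetry_alpha`, requiring at least 3
#' studies.  Under the default `"corroborated"` policy the flag fires —
#' and grade C follows — only when the asymmetry signal can actually
#' invalidate the association, operationalized as loss of significance
#' when re-pooling the most precise half of the studies; an asymmetry
#' signal that the large studies survive is recorded in `asymmetry_p`
#' but does not flag.  `pub_bias_policy = "signal"` makes the raw
#' P < `asymmetry_alpha` signal flag directly.
#'
#' Grade C requires a sensitivity or publication-bias flag; a low OR
#' alone does not invalidate an association (well-replicated protective
#' effects of modest size would otherwise be downgraded) but it does
#' preclude grade A, unless `low_or_policy = "strict"`.  Grade B is also
#' assigned when important information is missing for the appraisal: no
#' genotype data for the HWE check, or fewer than 3 studies for the
#' asymmetry test.  Grade A requires all four checks evaluable and no
#' flag.
#'
#' @param studies Study table rows of one SNP (k >= 2), ideally with the
#'   genotype block.
#' @param low_or_threshold Low-OR criterion threshold (default 1.15).
#' @param low_or_policy `"corroborated"` (default: a low OR alone gives
#'   grade B) or `"strict"` (a low OR alone gives grade C).
#' @param hwe_alpha Per-control-group HWE exact-test level (default 0.05).
#' @param asymmetry_alpha Funnel-asymmetry test level (default 0.10).
#' @param pub_bias_test `"harbord"` (default) or `"egger"`.
#' @param pub_bias_policy `"corroborated"` (default) or `"signal"`.
#' @return An object of class `"bias_assessment"`: list with the four
#'   flags, `asymmetry_p` and `asymmetry_test` (NA when infeasible),
#'   per-study `hwe_p`, `evaluable` (named logicals), and `grade`.
#' @export
assess_bias <- function(studies, low_or_threshold = 1.15,
                        low_or_policy = c("corroborated", "strict"),
                        hwe_alpha = 0.05, asymmetry_alpha = 0.10,
                        pub_bias_test = c("harbord", "egger"),
                        pub_bias_policy = c("corroborated", "signal")) {
  low_or_policy <- match.arg(low_or_policy)
  pub_bias_test <- match.arg(pub_bias_test)
  pub_bias_policy <- match.arg(pub_bias_policy)
  k <- nrow(studies)
  if (k < 2L) stop("bias assessment needs at least 2 studies",
                   call. = FALSE)
  eff <- study_effects(studies)
  full <- pool_dersimonian_laird(eff$log_or, eff$var_log_or)
  full_sig <- ci_excludes_null(full$ci_low, full$ci_high)

  significance_after_dropping <- function(drop_idx) {
    keep <- setdiff(seq_len(k), drop_idx)
    if (length(keep) == 0L) return(FALSE)
    if (length(keep) == 1L) {
      ci <- single_study_ci(eff$log_or[keep], eff$var_log_or[keep])
      return(ci_excludes_null(ci[1], ci[2]))
    }
    m <- pool_dersimonian_laird(eff$log_or[keep], eff$var_log_or[keep])
    ci_excludes_null(m$ci_low, m$ci_high)
  }

  low_or_flag <- max(full$pooled_or, 1 / full$pooled_or) < low_or_threshold

  first_idx <- order(eff$year, eff$study_id)[1]
  first_study_sensitivity <- full_sig &&
    !significance_after_dropping(first_idx)

  has_geno <- all(study_genotype_cols %in% names(studies))
  if (has_geno) {
    hwe_p <- vapply(seq_len(k), function(i) {
      hwe_exact_test(studies$control_hom_minor[i], studies$control_het[i],
                     studies$control_hom_major[i])
    }, numeric(1))
    violators <- which(hwe_p < hwe_alpha)
    hwe_sensitivity <- if (length(violators) == 0L) FALSE else {
      full_sig && !significance_after_dropping(violators)
    }
  } else {
    hwe_p <- rep(NA_real_, k)
    hwe_sensitivity <- NA
  }

  if (k >= 3L) {
    asymmetry_p <- if (pub_bias_test == "harbord") {
      harbord_test(studies$case_minor, studies$case_major,
                   studies$control_minor, studies$control_major)$p_value
    } else {
      egger_test(eff$log_or, eff$var_log_or)$p_value
    }
    signal <- asymmetry_p < asymmetry_alpha
    if (pub_bias_policy == "signal") {
      pub_bias_flag <- signal
    } else if (!signal) {
      pub_bias_flag <- FALSE
    } else {
      # clear bias must be able to invalidate the association: does it
      # survive on the most precise half of the studies?
      precise <- order(eff$var_log_or)[seq_len(max(2L, ceiling(k / 2)))]
      pub_bias_flag <- full_sig &&
        !significance_after_dropping(setdiff(seq_len(k), precise))
    }
  } else {
    asymmetry_p <- NA_real_
    pub_bias_flag <- NA
  }

  evaluable <- c(low_or = TRUE, first_study = TRUE,
                 hwe = has_geno, publication = k >= 3L)
  hard_flags <- c(first_study_sensitivity,
                  isTRUE(hwe_sensitivity), isTRUE(pub_bias_flag))
  grade <- if (any(hard_flags) ||
               (low_or_policy == "strict" && low_or_flag)) {
    "C"
  } else if (!all(evaluable) || low_or_flag) {
    "B"
  } else {
    "A"
  }
  structure(list(low_or_flag = low_or_flag,
                 first_study_sensitivity = first_study_sensitivity,
                 hwe_sensitivity = hwe_sensitivity,
                 pub_bias_flag = pub_bias_flag,
                 asymmetry_p = asymmetry_p, asymmetry_test = pub_bias_test,
                 hwe_p = hwe_p,
                 evaluable = evaluable, grade = grade),
            class = "bias_assessment")
}

#' @export
print.bias_assessment <- function(x, ...) {
  cat("bias assessment: grade", x$grade, "\n")
  cat(sprintf("  low OR: %s | first-study sensitivity: %s | HWE sensitivity: %s | publication bias: %s\n",
              x$low_or_flag, x$first_study_sensitivity,
              x$hwe_sensitivity, x$pub_bias_flag))
  invisible(x)
}

#' Overall epidemiologic credibility
#'
#' Combines the three axis grades: overall "A" (strong) only when all
#' three axes are A; "C" (weak) when any axis is C; "B" (moderate)
#' otherwise.  The quality string concatenates the axes in
#' amount / consistency / bias order.
#'
#' @param amount,consistency,bias Grade letters (vectorized).
#' @return `data.frame` with `amount`, `consistency`, `bias`, `overall`,
#'   `quality_string`.
#' @examples
#' overall_credibility("A", "A", "A")   # "AAA", overall A
#' overall_credibility("B", "A", "A")   # "BAA", overall B
#' @export
overall_credibility <- function(amount, consistency, bias) {
  check <- function(g, nm) {
    if (!all(g %in% c("A", "B", "C"))) {
      stop(sprintf("'%s' grades must be A, B or C", nm), call. = FALSE)
    }
    g
  }
  amount <- check(amount, "amount")
  consistency <- check(consistency, "consistency")
  bias <- check(bias, "bias")
  overall <- ifelse(amount == "C" | consistency == "C" | bias == "C", "C",
                    ifelse(amount == "A" & consistency == "A" &
                             bias == "A", "A", "B"))
  data.frame(amount = amount, consistency = consistency, bias = bias,
             overall = overall,
             quality_string = paste0(amount, consistency, bias),
             stringsAsFactors = FALSE)
}

#' Meta-analysis eligibility filter
#'
#' A SNP enters meta-analysis when its pooled minor-allele frequency in
#' healthy controls exceeds `maf_min` and case-control data are available
#' in at least `min_studies` independent samples.
#'
#' @param studies Study table (may hold many SNPs).
#' @param maf_min Control MAF threshold (default 0.01, strict >).
#' @param min_studies Minimum independent samples (default 4).
#' @return Character vector of eligible SNP ids.
#' @export
eligibility_filter <- function(studies, maf_min = 0.01, min_studies = 4L) {
  snps <- unique(studies$snp)
  keep <- vapply(snps, function(s) {
    sub <- studies[studies$snp == s, , drop = FALSE]
    nrow(sub) >= min_studies &&
      isTRUE(pooled_control_maf(sub) > maf_min)
  }, logical(1))
  snps[keep]
}

#' Best SNP of a gene
#'
#' Among the SNPs of one gene whose all-stratum or any single-stratum
#' 95\% CI excludes OR = 1, returns the SNP with the smallest all-stratum
#' pooled P value; ties break by rsID lexical order.  Returns `NULL` when
#' no SNP is significant (the gene is then excluded from the top list).
#'
#' @param gene_results `data.frame` of stratified results for one gene
#'   (columns of [stratified_meta()] plus `snp`).
#' @return The chosen SNP id, or `NULL`.
#' @export
select_best_snp <- function(gene_results) {
  sig_snps <- unique(gene_results$snp[
    ci_excludes_null(gene_results$ci_low, gene_results$ci_high) &
      !is.na(gene_results$or)])
  if (!length(sig_snps)) return(NULL)
  all_rows <- gene_results[gene_results$stratum == "all" &
                             gene_results$snp %in% sig_snps, , drop = FALSE]
  all_rows <- all_rows[order(all_rows$p, all_rows$snp), , drop = FALSE]
  all_rows$snp[1]
}

#' Rank a graded gene list
#'
#' Orders loci by overall credibility grade (A before B before C) and,
#' within a grade, by ascending pooled P value; gene symbol breaks exact
#' ties so the order is fully deterministic.
#'
#' @param graded `data.frame` with at least `gene`, `overall`, `p`.
#' @return The reordered `data.frame`.
#' @export
rank_top_list <- function(graded) {
  stopifnot(all(c("gene", "overall", "p") %in% names(graded)))
  out <- graded[order(match(graded$overall, c("A", "B", "C")), graded$p,
                      graded$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
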