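#' Per-study allele-contrast log odds ratio
#'
#' Computes `log(ad / bc)` and its large-sample variance
#' `1/a + 1/b + 1/c + 1/d` from the 2x2 allele table (a = case minor,
#' b = case major, c = control minor, d = control major).  If any cell is
#' zero the Haldane-Anscombe continuity correction adds 0.5 to all four
#' cells and the `corrected` flag is set.  An empty margin (no case
#' alleles or no control alleles) is an error.
#'
#' @param case_minor,case_major,control_minor,control_major Non-negative
#'   allele counts (vectorized).
#' @return `data.frame` with columns `log_or`, `var_log_or`, `corrected`.
#' @examples
#' study_log_or(20, 80, 10, 90)  # OR 2.25
#' @export
study_log_or <- function(case_minor, case_major, control_minor,
                         control_major) {
  a <- as.numeric(case_minor); b <- as.numeric(case_major)
  c_ <- as.numeric(control_minor); d <- as.numeric(control_major)
  n <- length(a)
  if (any(c(a, b, c_, d) < 0) || anyNA(c(a, b, c_, d))) {
    stop("allele counts must be non-negative and non-missing",
         call. = FALSE)
  }
  if (any(a + b == 0) || any(c_ + d == 0)) {
    stop("empty margin: a study with no case or no control alleles",
         call. = FALSE)
  }
  corrected <- a == 0 | b == 0 | c_ == 0 | d == 0
  a[corrected] <- a[corrected] + 0.5
  b[corrected] <- b[corrected] + 0.5
  c_[corrected] <- c_[corrected] + 0.5
  d[corrected] <- d[corrected] + 0.5
  data.frame(log_or = log(a * d / (b * c_)),
             var_log_or = 1 / a + 1 / b + 1 / c_ + 1 / d,
             corrected = corrected)
}

#' Study effects with metadata and single-study confidence intervals
#'
#' Applies [study_log_or()] to each row of a study table and carries the
#' study metadata through, adding the per-study Wald 95\% CI on the OR
#' scale (the per-study significance notion used by the publication
#' filter and the bias assessment).
#'
#' @param studies A validated study table.
#' @return `data.frame` with `study_id`, `population`, `year`, `log_or`,
#'   `var_log_or`, `corrected`, `ci_low`, `ci_high`.
#' @export
study_effects <- function(studies) {
  eff <- study_log_or(studies$case_minor, studies$case_major,
                      studies$control_minor, studies$control_major)
  half <- 1.96 * sqrt(eff$var_log_or)
  data.frame(study_id = studies$study_id,
             population = studies$population,
             year = studies$year,
             eff,
             ci_low = exp(eff$log_or - half),
             ci_high = exp(eff$log_or + half),
             stringsAsFactors = FALSE)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Method-of-moments random-effects meta-analysis of study log odds
#' ratios.  Fixed-effect weights are `w_i = 1/v_i`; Cochran's
#' `Q = sum w_i (y_i - y_FE)^2`; the between-study variance is
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`; random
#' weights `1/(v_i + tau2)` give the pooled estimate, a z-based 95\% CI,
#' and a two-sided normal P value, all reported on the OR scale.
#'
#' @param log_or Numeric vector of study log odds ratios (k >= 2).
#' @param var_log_or Positive sampling variances, same length.
#' @return An object of class `"meta_result"`: a list with `pooled_or`,
#'   `ci_low`, `ci_high`, `p_value`, `q_stat`, `tau2`, `i2`, `k`,
#'   `log_pooled`, `var_pooled`.
#' @examples
#' pool_dersimonian_laird(c(0.2, 0.6, 0.4), c(0.04, 0.09, 0.05))
#' @export
pool_dersimonian_laird <- function(log_or, var_log_or) {
  k <- length(log_or)
  if (k != length(var_log_or)) stop("length mismatch", call. = FALSE)
  if (k < 2L) {
    stop("at least 2 studies are required to pool; use the single-study ",
         "effect directly", call. = FALSE)
  }
  if (any(!is.finite(log_or)) || any(!is.finite(var_log_or)) ||
      any(var_log_or <= 0)) {
    stop("effects must be finite with positive variances", call. = FALSE)
  }
  w <- 1 / var_log_or
  y_fe <- sum(w * log_or) / sum(w)
  q <- sum(w * (log_or - y_fe)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  w_re <- 1 / (var_log_or + tau2)
  est <- sum(w_re * log_or) / sum(w_re)
  v_est <- 1 / sum(w_re)
  z <- est / sqrt(v_est)
  structure(list(
    pooled_or = exp(est),
    ci_low = exp(est - 1.96 * sqrt(v_est)),
    ci_high = exp(est + 1.96 * sqrt(v_est)),
    p_value = 2 * stats::pnorm(-abs(z)),
    q_stat = q,
    tau2 = tau2,
    i2 = heterogeneity_i2(q, k),
    k = k,
    log_pooled = est,
    var_pooled = v_est
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "random-effects pooled OR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
    x$pooled_or, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("k = %d studies, Q = %.3f, tau2 = %.4f, I2 = %.1f%%\n",
              x$k, x$q_stat, x$tau2, x$i2))
  invisible(x)
}

#' I-squared heterogeneity percentage
#'
#' `I2 = max(0, (Q - (k - 1)) / Q) * 100`, with `I2 = 0` when `Q = 0`:
#' the percentage of total variation across studies attributable to
#' between-study heterogeneity rather than chance.
#'
#' @param q_stat Non-negative Cochran's Q.
#' @param k Number of studies (>= 2).
#' @return Percentage in [0, 100].
#' @export
heterogeneity_i2 <- function(q_stat, k) {
  stop_if_not_scalar_number(q_stat, "q_stat", lower = 0)
  stop_if_not_scalar_number(k, "k", lower = 2)
  if (q_stat == 0) return(0)
  max(0, (q_stat - (k - 1)) / q_stat) * 100
}

#' Population-stratified random-effects meta-analysis for one SNP
#'
#' Pools every population stratum with at least two studies, plus an
#' `"all"` stratum pooling every study directly.  Strata with fewer than
#' two studies are reported with `NA` results (printed as "n.a" in the
#' top-list output), mirroring the convention "one study or none;
#' meta-analysis could not be performed".  `n_minor` is the total minor
#' allele count of cases and controls combined in the pooled studies.
#'
#' @param studies Study table rows sharing one SNP.
#' @return `data.frame` with one row per stratum: `stratum`, `k`,
#'   `n_minor`, `or`, `ci_low`, `ci_high`, `p`, `q`, `tau2`, `i2`.
#' @export
stratified_meta <- function(studies) {
  if (length(unique(studies$snp)) != 1L) {
    stop("stratified_meta expects studies of a single SNP", call. = FALSE)
  }
  eff <- study_effects(studies)
  strata <- c(sort(unique(studies$population)), "all")
  rows <- lapply(strata, function(s) {
    idx <- if (s == "all") seq_len(nrow(studies)) else
      which(studies$population == s)
    n_minor <- sum(studies$case_minor[idx] + studies$control_minor[idx])
    if (length(idx) < 2L) {
      return(data.frame(stratum = s, k = length(idx), n_minor = n_minor,
                        or = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_, q = NA_real_,
                        tau2 = NA_real_, i2 = NA_real_,
                        stringsAsFactors = FALSE))
    }
    m <- pool_dersimonian_laird(eff$log_or[idx], eff$var_log_or[idx])
    data.frame(stratum = s, k = m$k, n_minor = n_minor, or = m$pooled_or,
               ci_low = m$ci_low, ci_high = m$ci_high, p = m$p_value,
               q = m$q_stat, tau2 = m$tau2, i2 = m$i2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Gene-wide minor allele orientation
#'
#' Defines the minor allele from pooled control frequencies across all
#' studies of a SNP, so the contrast direction is identical in every
#' study.  If the labelled "minor" allele has pooled control frequency
#' above 0.5 the allele and genotype columns are swapped.
#'
#' @param studies Study table rows sharing one SNP.
#' @return The possibly reoriented study table.
#' @export
orient_minor_allele <- function(studies) {
  maf <- pooled_control_maf(studies)
  if (is.na(maf) || maf <= 0.5) return(studies)
  swap <- function(df, one, two) {
    tmp <- df[[one]]; df[[one]] <- df[[two]]; df[[two]] <- tmp; df
  }
  studies <- swap(studies, "case_minor", "case_major")
  studies <- swap(studies, "control_minor", "control_major")
  if (all(study_genotype_cols %in% names(studies))) {
    studies <- swap(studies, "case_hom_minor", "case_hom_major")
    studies <- swap(studies, "control_hom_minor", "control_hom_major")
  }
  studies
}

# Pooled minor-allele frequency in controls across studies of one SNP.
pooled_control_maf <- function(studies) {
  tot <- sum(studies$control_minor + studies$control_major)
  if (tot == 0) return(NA_real_)
  sum(studies$control_minor) / tot
}
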