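#' Simulation settings for multi-study case-control genotype data
#'
#' Bundles the ground-truth parameters of a simulated evidence base for one
#' SNP: a pooled allele-contrast odds ratio, between-study variance of the
#' log odds ratio, per-study sample sizes, the control minor-allele
#' frequency, an optional inbreeding-style departure from Hardy-Weinberg
#' equilibrium in controls, and an optional strength of
#' significance-dependent study retention (publication bias).
#'
#' @param true_or Positive pooled odds ratio (allele contrast).
#' @param tau2 Non-negative between-study variance of the study log odds
#'   ratios.
#' @param k_studies Number of independent study samples to simulate.
#' @param n_cases,n_controls Per-study sample sizes (individuals); a scalar
#'   is recycled, or supply one value per study.
#' @param control_maf Minor-allele frequency in controls, in (0, 0.5].
#' @param hwe_inbreeding Inbreeding coefficient F in [0, 1) applied to the
#'   control genotype frequencies; 0 means controls are in exact HWE.
#' @param pub_bias_gamma Non-negative strength of significance-dependent
#'   study retention; 0 retains every study (see
#'   [apply_publication_filter()]).
#' @param gene,snp Labels carried into the simulated study table.
#' @param populations Population label(s), recycled across studies; must be
#'   drawn from the controlled vocabulary (see [population_levels()]).
#' @param year_start First publication year; studies are dated sequentially
#'   so that the "first study" used by the bias assessment is well defined.
#' @param seed Integer seed; the simulation is fully deterministic given it.
#'
#' @return An object of class `"simulation_config"` (a validated list).
#' @seealso [simulate_gene_studies()]
#' @export
simulation_config <- function(true_or = 1.2, tau2 = 0, k_studies = 8L,
                              n_cases = 1000L, n_controls = 1000L,
                              control_maf = 0.3, hwe_inbreeding = 0,
                              pub_bias_gamma = 0,
                              gene = "GENE1", snp = "rs1000001",
                              populations = "Caucasian",
                              year_start = 1995L, seed = 1L) {
  stop_if_not_scalar_number(true_or, "true_or", lower = 0, lower_open = TRUE)
  stop_if_not_scalar_number(tau2, "tau2", lower = 0)
  stop_if_not_scalar_number(k_studies, "k_studies", lower = 1)
  stop_if_not_scalar_number(control_maf, "control_maf",
                            lower = 0, upper = 0.5, lower_open = TRUE)
  stop_if_not_scalar_number(hwe_inbreeding, "hwe_inbreeding",
                            lower = 0, upper = 1, upper_open = TRUE)
  stop_if_not_scalar_number(pub_bias_gamma, "pub_bias_gamma", lower = 0)
  stop_if_not_scalar_number(year_start, "year_start")
  stop_if_not_scalar_number(seed, "seed")
  k <- as.integer(k_studies)
  n_cases <- as.integer(rep_len(n_cases, k))
  n_controls <- as.integer(rep_len(n_controls, k))
  if (any(!is.finite(n_cases)) || any(n_cases < 1L) ||
      any(!is.finite(n_controls)) || any(n_controls < 1L)) {
    stop("per-study sample sizes must be positive integers", call. = FALSE)
  }
  populations <- rep_len(as.character(populations), k)
  bad <- setdiff(unique(populations), population_levels())
  if (length(bad)) {
    stop("unknown population label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(true_or = true_or, tau2 = tau2, k_studies = k,
                 n_cases = n_cases, n_controls = n_controls,
                 control_maf = control_maf, hwe_inbreeding = hwe_inbreeding,
                 pub_bias_gamma = pub_bias_gamma, gene = gene, snp = snp,
                 populations = populations,
                 year_start = as.integer(year_start),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Genotype frequencies (hom minor, het, hom major) at minor-allele
# frequency p with inbreeding coefficient f.
genotype_freqs <- function(p, f = 0) {
  q <- 1 - p
  c(p^2 + f * p * q, 2 * p * q * (1 - f), q^2 + f * p * q)
}

#' Simulate a multi-study case-control evidence base for one SNP
#'
#' Genotypes, not alleles, are the primitive simulated unit so that HWE
#' testing on control groups is meaningful; allele counts are derived as
#' 2 x (hom count) + (het count).  For each study a log odds ratio is drawn
#' from Normal(log(true_or), tau2); control genotypes are multinomial at
#' the control MAF (with optional inbreeding-coefficient departure from
#' HWE), and case genotypes are always drawn under HWE at the case allele
#' frequency implied by the study's odds ratio:
#' p_case = p e^theta / (1 - p + p e^theta).
#'
#' @param config A [simulation_config()].
#' @return A study table (`data.frame`) with one row per study and the
#'   columns documented in [read_study_table()], including the genotype
#'   block.
#' @examples
#' cfg <- simulation_config(true_or = 1.5, k_studies = 4, seed = 42)
#' studies <- simulate_gene_studies(cfg)
#' studies$case_minor / (studies$case_minor + studies$case_major)
#' @export
simulate_gene_studies <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("'config' must be created by simulation_config()", call. = FALSE)
  }
  k <- config$k_studies
  with_preserved_seed(config$seed, {
    theta <- stats::rnorm(k, mean = log(config$true_or),
                          sd = sqrt(config$tau2))
    p <- config$control_maf
    p_case <- p * exp(theta) / (1 - p + p * exp(theta))
    ctrl <- vapply(seq_len(k), function(i) {
      stats::rmultinom(1, config$n_controls[i],
                       genotype_freqs(p, config$hwe_inbreeding))[, 1]
    }, integer(3))
    case <- vapply(seq_len(k), function(i) {
      stats::rmultinom(1, config$n_cases[i], genotype_freqs(p_case[i]))[, 1]
    }, integer(3))
    data.frame(
      gene = config$gene,
      snp = config$snp,
      study_id = sprintf("%s_study_%02d", config$gene, seq_len(k)),
      population = config$populations,
      year = config$year_start + seq_len(k) - 1L,
      case_minor = 2L * case[1, ] + case[2, ],
      case_major = 2L * case[3, ] + case[2, ],
      control_minor = 2L * ctrl[1, ] + ctrl[2, ],
      control_major = 2L * ctrl[3, ] + ctrl[2, ],
      case_hom_minor = case[1, ], case_het = case[2, ],
      case_hom_major = case[3, ],
      control_hom_minor = ctrl[1, ], control_het = ctrl[2, ],
      control_hom_major = ctrl[3, ],
      stringsAsFactors = FALSE
    )
  })
}

#' Significance-dependent study retention (publication filtering)
#'
#' Retains study i with probability
#' `min(1, exp(-gamma) + (1 - exp(-gamma)) * sig_i)` where `sig_i` is 1
#' when the study's own 95\% confidence interval excludes OR = 1 and 0
#' otherwise.  `gamma = 0` retains every study; very large `gamma` retains
#' only individually significant studies.
#'
#' @param studies A study table as returned by [simulate_gene_studies()].
#' @param gamma Non-negative retention strength.
#' @param seed Integer seed; retention is deterministic given it.
#' @return The retained subset of `studies` (rows, original order).
#' @export
apply_publication_filter <- function(studies, gamma, seed = 1L) {
  stop_if_not_scalar_number(gamma, "gamma", lower = 0)
  if (nrow(studies) == 0L || gamma == 0) {
    return(studies)
  }
  eff <- study_effects(studies)
  sig <- as.numeric(ci_excludes_null(eff$ci_low, eff$ci_high))
  keep_prob <- pmin(1, exp(-gamma) + (1 - exp(-gamma)) * sig)
  with_preserved_seed(seed, {
    keep <- stats::runif(nrow(studies)) < keep_prob
    studies[keep, , drop = FALSE]
  })
}

#' Simulate a toy annotation universe with planted enriched terms
#'
#' Builds a background universe of genes, a small `is_a` ontology holding
#' the planted terms (all children of a single root), and gene-to-term
#' annotations in which the planted terms preferentially annotate the test
#' genes, so that downstream over-representation has known ground truth.
#' A planted term of size g annotates the test genes first (up to g) and
#' fills the remainder with randomly chosen background genes.  Every gene
#' additionally receives one uniformly chosen "filler" term so the
#' annotation-defined universe covers all genes.
#'
#' @param n_background Total number of genes in the universe (test genes
#'   included; must be at least `length(test_genes)`).
#' @param planted_terms Named integer vector: term id -> number of genes
#'   annotated to it.  Duplicate ids are rejected.
#' @param test_genes Character vector of focal gene ids.
#' @param seed Integer seed.
#' @param n_filler_terms Number of uniform background terms.
#' @return A list with components `annotations` (an `annotation_set`) and
#'   `dag` (an `ontology_dag`).
#' @export
simulate_annotation_universe <- function(n_background, planted_terms = NULL,
                                         test_genes = character(), seed = 1L,
                                         n_filler_terms = 5L) {
  stop_if_not_scalar_number(n_background, "n_background", lower = 1)
  n_background <- as.integer(n_background)
  test_genes <- as.character(test_genes)
  if (length(test_genes) > n_background) {
    stop("more test genes than background universe size", call. = FALSE)
  }
  sizes <- integer(0)
  if (length(planted_terms)) {
    sizes <- as.integer(planted_terms)
    ids <- names(planted_terms)
    if (is.null(ids) || anyDuplicated(ids)) {
      stop("planted_terms must be uniquely named (term id -> gene count)",
           call. = FALSE)
    }
    if (any(sizes < 1L) || any(sizes > n_background)) {
      stop("planted term gene counts must be in [1, n_background]",
           call. = FALSE)
    }
    names(sizes) <- ids
  }
  n_extra <- n_background - length(test_genes)
  universe <- c(test_genes,
                if (n_extra > 0) sprintf("BG%05d", seq_len(n_extra)))
  root <- "SIM:0000000"
  filler <- sprintf("SIM:9%06d", seq_len(n_filler_terms))
  term_ids <- c(root, names(sizes), filler)
  terms <- data.frame(
    id = term_ids,
    name = c("simulated biological process root",
             if (length(sizes)) paste("planted term", names(sizes)),
             paste("filler process", seq_len(n_filler_terms))),
    namespace = "biological_process",
    obsolete = FALSE, stringsAsFactors = FALSE)
  parents <- c(list(character(0)),
               rep(list(root), length(term_ids) - 1L))
  names(parents) <- term_ids
  dag <- new_ontology_dag(terms, parents)
  with_preserved_seed(seed, {
    pairs <- data.frame(gene = universe,
                        term = sample(filler, n_background, replace = TRUE),
                        stringsAsFactors = FALSE)
    for (id in names(sizes)) {
      g <- sizes[[id]]
      chosen <- if (g <= length(test_genes)) {
        test_genes[seq_len(g)]
      } else {
        c(test_genes,
          sample(setdiff(universe, test_genes), g - length(test_genes)))
      }
      pairs <- rbind(pairs, data.frame(gene = chosen, term = id,
                                       stringsAsFactors = FALSE))
    }
    list(annotations = annotation_set(pairs, universe), dag = dag)
  })
}
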