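test_that("amount grade honours the published boundaries", {
  expect_equal(amount_grade(4167), "A")   # strongest published locus
  expect_equal(amount_grade(227), "B")
  expect_equal(amount_grade(c(99, 100, 1000, 1001)),
               c("C", "B", "B", "A"))
  expect_error(amount_grade(-1), "non-negative")
})

test_that("consistency grade honours the published boundaries", {
  expect_equal(consistency_grade(13), "A")
  expect_equal(consistency_grade(c(24.99, 25, 50, 50.01, 60)),
               c("A", "B", "B", "C", "C"))
  expect_error(consistency_grade(101), "percentage")
})

test_that("grades are monotone in their inputs", {
  n <- sort(sample(0:5000, 50))
  g <- match(amount_grade(n), c("A", "B", "C"))
  expect_true(all(diff(g) <= 0))
  i2 <- sort(runif(50, 0, 100))
  g2 <- match(consistency_grade(i2), c("A", "B", "C"))
  expect_true(all(diff(g2) >= 0))
})

test_that("overall credibility combines the three axes per the stated rule", {
  res <- overall_credibility(c("A", "B", "A", "A", "C", "B"),
                             c("A", "A", "C", "A", "A", "B"),
                             c("A", "A", "A", "B", "A", "C"))
  expect_equal(res$overall, c("A", "B", "C", "B", "C", "C"))
  expect_equal(res$quality_string[1:2], c("AAA", "BAA"))
  expect_error(overall_credibility("A", "D", "A"), "grades")
})

test_that("Egger and Harbord tests agree with the independent reference implementation", {
  skip_if_not_installed("metafor")
  s <- clean_gene(5007)
  e <- study_effects(s)
  mine <- egger_test(e$log_or, e$var_log_or)
  ref <- metafor::regtest(metafor::rma(yi = e$log_or, vi = e$var_log_or,
                                       method = "DL"), model = "lm")
  expect_equal(mine$p_value, ref$pval, tolerance = 1e-8)
  expect_error(egger_test(c(0.1, 0.2), c(0.1, 0.1)), "at least 3")
  h <- harbord_test(s$case_minor, s$case_major, s$control_minor,
                    s$control_major)
  expect_true(h$p_value > 0 && h$p_value <= 1)
})

test_that("a clean well-powered evidence base earns bias grade A", {
  b <- assess_bias(clean_gene(881))
  expect_false(b$low_or_flag)
  expect_false(b$first_study_sensitivity)
  expect_false(isTRUE(b$hwe_sensitivity))
  expect_false(isTRUE(b$pub_bias_flag))
  expect_equal(b$grade, "A")
})

test_that("two studies cannot support a full appraisal: grade B", {
  s <- clean_gene(882, k = 2)
  b <- assess_bias(s)
  expect_true(is.na(b$asymmetry_p))
  expect_equal(b$grade, "B")
  expect_error(assess_bias(s[1, ]), "at least 2")
})

test_that("missing genotype data caps the grade at B", {
  s <- clean_gene(883)
  b <- assess_bias(s[, !(names(s) %in% c(
    "case_hom_minor", "case_het", "case_hom_major",
    "control_hom_minor", "control_het", "control_hom_major"))])
  expect_true(is.na(b$hwe_sensitivity))
  expect_equal(b$grade, "B")
})

test_that("a modest OR alone yields grade B under the default policy, C under strict", {
  s <- clean_gene(884, true_or = 1.08, k = 10, n = 30000)
  b <- assess_bias(s)
  expect_true(b$low_or_flag)
  expect_false(b$first_study_sensitivity)
  expect_equal(b$grade, "B")
  expect_equal(assess_bias(s, low_or_policy = "strict")$grade, "C")
})

test_that("a dominant first study carrying all the signal is flagged and downgrades to C", {
  s <- dominant_first_fixture()
  eff <- study_effects(s)
  full <- pool_dersimonian_laird(eff$log_or, eff$var_log_or)
  expect_gt(full$ci_low, 1)   # pooled association is significant
  b <- assess_bias(s)
  expect_true(b$first_study_sensitivity)
  expect_equal(b$grade, "C")
})

test_that("HWE-violating control groups that carry the signal are flagged", {
  # the only informative study has a strong heterozygote deficit in its
  # controls; the tiny replications cannot sustain the association alone
  bad <- make_study("violator_1997",
                    case = c(306L, 953L, 741L),
                    control = c(400L, 400L, 1200L), year = 1997L)
  nulls <- lapply(c(1995L, 1996L, 1998L), function(yr) {
    make_study(sprintf("tiny_%d", yr), case = c(2L, 11L, 12L),
               control = c(2L, 11L, 12L), year = yr)
  })
  s <- rbind(do.call(rbind, nulls), bad)
  expect_lt(hwe_exact_test(400, 400, 1200), 1e-10)
  b <- assess_bias(s)
  expect_false(b$first_study_sensitivity)  # earliest study is a tiny null
  expect_true(isTRUE(b$hwe_sensitivity))
  expect_equal(b$grade, "C")
})

test_that("an asymmetric funnel whose association fails on the precise half is publication-bias grade C", {
  s <- asymmetric_small_study_fixture()
  eff <- study_effects(s)
  full <- pool_dersimonian_laird(eff$log_or, eff$var_log_or)
  expect_gt(full$ci_low, 1)
  b <- assess_bias(s)
  expect_lt(b$asymmetry_p, 0.10)
  expect_true(isTRUE(b$pub_bias_flag))
  expect_equal(b$grade, "C")
  # under the literal signal policy the flag fires from the test alone
  expect_true(isTRUE(assess_bias(s, pub_bias_policy = "signal")$pub_bias_flag))
})

test_that("eligibility requires four samples and control MAF above 1 percent", {
  s3 <- simulate_gene_studies(simulation_config(k_studies = 3, seed = 91))
  expect_length(eligibility_filter(s3), 0)
  s5 <- simulate_gene_studies(simulation_config(k_studies = 5, seed = 92))
  expect_equal(eligibility_filter(s5), s5$snp[1])
  rare <- simulate_gene_studies(simulation_config(
    k_studies = 5, control_maf = 0.005, n_controls = 4000, seed = 93))
  expect_length(eligibility_filter(rare), 0)
})

test_that("best SNP selection minimizes pooled P among significant SNPs", {
  mk <- function(snp, p, lo, hi) {
    data.frame(snp = snp, stratum = "all", or = (lo + hi) / 2,
               ci_low = lo, ci_high = hi, p = p,
               stringsAsFactors = FALSE)
  }
  res <- rbind(mk("rs2", 1e-3, 1.1, 1.5), mk("rs1", 1e-5, 1.2, 1.6),
               mk("rs3", 0.2, 0.9, 1.4))
  expect_equal(select_best_snp(res), "rs1")
  expect_null(select_best_snp(mk("rs9", 0.4, 0.8, 1.2)))
  # ties break lexically by rsID
  tie <- rbind(mk("rsB", 1e-4, 1.1, 1.5), mk("rsA", 1e-4, 1.1, 1.5))
  expect_equal(select_best_snp(tie), "rsA")
  # brute-force ordering oracle over shuffled inputs
  set.seed(9)
  ps <- c(rs10 = 1e-6, rs11 = 1e-2, rs12 = 1e-4)
  res <- do.call(rbind, lapply(names(ps), function(s) {
    mk(s, ps[[s]], 1.05, 1.5)
  }))
  for (i in 1:5) {
    expect_equal(select_best_snp(res[sample(nrow(res)), ]),
                 names(which.min(ps)))
  }
})

test_that("ranking orders by grade then P value, stably under permutation", {
  g <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                  overall = c("B", "A", "A", "C"),
                  p = c(1e-8, 1e-4, 1e-6, 1e-10),
                  stringsAsFactors = FALSE)
  ranked <- rank_top_list(g)
  expect_equal(ranked$gene, c("g3", "g2", "g1", "g4"))
  set.seed(3)
  expect_equal(rank_top_list(g[sample(4), ]), ranked)
})
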