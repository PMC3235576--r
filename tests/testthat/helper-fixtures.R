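# Construct study rows from genotype triples (hom minor, het, hom major);
# allele counts are derived so the count invariant holds by construction.
make_study <- function(study_id, case, control, gene = "G1", snp = "rs1",
                       population = "Caucasian", year = 2000L) {
  data.frame(gene = gene, snp = snp, study_id = study_id,
             population = population, year = year,
             case_minor = 2L * case[1] + case[2],
             case_major = 2L * case[3] + case[2],
             control_minor = 2L * control[1] + control[2],
             control_major = 2L * control[3] + control[2],
             case_hom_minor = case[1], case_het = case[2],
             case_hom_major = case[3],
             control_hom_minor = control[1], control_het = control[2],
             control_hom_major = control[3],
             stringsAsFactors = FALSE)
}

# One large early study carrying an OR-1.5 signal plus three tiny null
# replications: pooled result is significant and driven entirely by the
# first study.
dominant_first_fixture <- function() {
  rbind(
    make_study("big_1995", case = c(306L, 953L, 741L),
               control = c(180L, 840L, 980L), year = 1995L),
    make_study("tiny_1996", case = c(2L, 11L, 12L),
               control = c(2L, 11L, 12L), year = 1996L),
    make_study("tiny_1997", case = c(2L, 11L, 12L),
               control = c(2L, 11L, 12L), year = 1997L),
    make_study("tiny_1998", case = c(2L, 11L, 12L),
               control = c(2L, 11L, 12L), year = 1998L))
}

# Three large null studies plus four small studies with inflated effects:
# the funnel is asymmetric and the association vanishes on the precise
# half — the signature of significance-driven selective publication.
asymmetric_small_study_fixture <- function() {
  large <- lapply(1:3, function(i) {
    make_study(sprintf("large_%d", i), case = c(180L, 840L, 980L),
               control = c(180L, 840L, 980L), year = 1994L + i)
  })
  small <- lapply(1:4, function(i) {
    make_study(sprintf("small_%d", i), case = c(27L, 49L, 24L),
               control = c(9L, 42L, 49L), year = 1997L + i)
  })
  do.call(rbind, c(large, small))
}

# A well-powered clean simulated evidence base (no planted bias).
clean_gene <- function(seed, true_or = 2, k = 8, n = 1000) {
  simulate_gene_studies(simulation_config(
    true_or = true_or, tau2 = 0, k_studies = k, n_cases = n,
    n_controls = n, control_maf = 0.3, seed = seed))
}
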