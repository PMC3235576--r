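---
title: "Credibility grading of genetic association evidence: models and design choices"
author: "credmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Credibility grading of genetic association evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(credmeta)
```

## The problem

Candidate-gene association databases for complex diseases such as
late-onset Alzheimer's disease accumulate hundreds of loci, each backed
by a heterogeneous pile of case-control studies of very different size
and quality. Most reported associations do not survive cumulative
scrutiny. `credmeta` implements the evidence-distillation pipeline used
in that setting: per-SNP random-effects meta-analysis of allele
contrasts, a three-axis A/B/C credibility grade per association
(HuGENet interim criteria), a ranked top-gene list, and a
shared-pathway stage that asks which biological processes the credible
genes have in common.

## Per-study effect and random-effects pooling

The evidence unit is the 2x2 allele table of one study: minor and major
allele counts in cases (a, b) and controls (c, d). The study effect is
the log odds ratio

$$y_i = \log\frac{a_i d_i}{b_i c_i}, \qquad
  v_i = \frac1{a_i}+\frac1{b_i}+\frac1{c_i}+\frac1{d_i}.$$

If any cell is zero, the Haldane–Anscombe correction adds 0.5 to all
four cells and the record is flagged. A study with no case or no
control alleles is an error, not a correction candidate. The minor
allele is defined once per SNP from pooled control frequencies, so the
contrast direction is identical across studies.

Studies are pooled with the DerSimonian–Laird method-of-moments model:
fixed weights $w_i = 1/v_i$ give Cochran's
$Q = \sum_i w_i (y_i - \hat y_{FE})^2$, the between-study variance is

$$\hat\tau^2 = \max\!\left(0,\;
  \frac{Q - (k-1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right),$$

and random weights $w_i^* = 1/(v_i + \hat\tau^2)$ yield the pooled
log OR, a z-based 95% CI and a two-sided normal P value, reported on
the OR scale. Consistency is summarized as
$I^2 = \max(0, (Q - (k-1))/Q) \cdot 100$, a point estimate only (no CI
around $I^2$), with $I^2 = 0$ when $Q = 0$. The z-based (not t-based)
interval matches the classical formulation of the model; at $k = 8$
and $\tau^2 = 0$ its empirical null coverage sits near 95%, which the
test suite measures directly.

Strata: each population with at least two studies is pooled
separately, and an `"all"` stratum pools every study directly (rather
than re-meta-analysing the stratum summaries — the convention chosen
here for the "all ethnic groups" column). A stratum with one study or
none prints `n.a`.

## The three grading axes

* **Amount of evidence** — `N minor`, the total minor allele count of
  cases and controls combined across the pooled studies: A above
  1,000, B from 100 to 1,000 inclusive, C below 100. The boundary
  1,000 itself is B ("exceeds 1,000" is required for A).
* **Consistency of replication** — the $I^2$ point estimate: A below
  25%, B from 25% to 50% inclusive, C above 50%.
* **Protection from bias** — four checks, detailed below.

Overall credibility is A (strong) only for three A's, C (weak) if any
axis is C, otherwise B (moderate). Loci are ranked by overall grade,
then ascending pooled P.

## The bias axis

Four potential reasons for bias are assessed on the best SNP of each
gene; "significant" always means the 95% CI excludes OR 1, and every
re-pooling is the full pooling computation on the reduced study set —
there are no incremental shortcuts.

1. **Low OR**: $\max(\mathrm{OR}, 1/\mathrm{OR}) < 1.15$. The
   criterion is deliberately symmetric: protective loci of modest
   effect (OR around 0.88) are graded A in the published table this
   pipeline mirrors, so a literal one-sided "OR < 1.15" rule would
   contradict the grades it is meant to reproduce. A low OR alone does
   not invalidate an association: it caps the grade at B under the
   default policy (`low_or_policy = "strict"` restores the harsher
   reading).
2. **First-study sensitivity**: the association loses significance
   when the earliest-published study (ties broken by study id) is
   removed. "Earliest year" is a convention; the source material does
   not say whether the first published or the discovery sample is
   meant.
3. **HWE sensitivity**: the association loses significance when
   studies whose *control* genotypes fail an exact Hardy–Weinberg test
   at P < 0.05 are removed. The exact (not chi-square) test is used
   for validity at small counts. Only control groups are inspected;
   the simulator mirrors this by allowing HWE violations in controls
   only.
4. **Publication bias**: a funnel-asymmetry screen plus an
   invalidation check, discussed next.

Grade C requires a fired sensitivity or publication-bias flag. Grade B
is assigned when important information is missing — no genotype data
for the HWE check, or fewer than three studies for the asymmetry test
— or when only the low-OR flag is raised. Grade A requires all four
checks evaluable and clean.

### Why Harbord's test, and why the flag needs corroboration

Egger's regression, the most familiar small-study-effect test, is a
poor default for odds ratios from 2x2 tables: the standard error of a
log OR is a deterministic function of the estimate itself, so estimate
and precision are correlated *by construction*, and the intercept test
rejects far above its nominal level as the true OR moves away from 1
— a failure mode well documented in the methodological literature.
The package therefore defaults to Harbord's score-based variant, which
regresses $Z/\sqrt V$ on $\sqrt V$ where $Z$ is the score and $V$ the
information of each table's conditional likelihood; score and
information are uncoupled and the test holds its level for the effect
sizes seen in this domain. Egger's version remains available
(`pub_bias_test = "egger"`) and both are cross-checked against an
independent reference implementation in the test suite.

Even a calibrated 10%-level screen would, by definition, flag about
one clean meta-analysis in ten. The grade-C definition this axis
implements is *evidence for clear bias that can invalidate the
association*, so under the default `"corroborated"` policy the flag
fires only when the asymmetry signal (P < 0.10) is accompanied by loss
of significance on the most precise half of the studies — i.e. when
the association genuinely stands on its small studies. An asymmetry
signal the large studies survive is recorded in `asymmetry_p` but
does not downgrade. `pub_bias_policy = "signal"` restores the literal
screen-only flag for sensitivity analyses.

## Exact Hardy–Weinberg test

Conditional on the observed allele counts, the heterozygote count
follows the Levene–Haldane distribution; the P value sums the
probabilities of all heterozygote counts (same parity as the rare
allele count) whose conditional probability does not exceed that of
the observed count. Probabilities are computed with log-gamma
accumulation and normalized in a numerically stable way; a relative
tolerance of 1e-12 guards the "as extreme" comparison against
floating-point ties. The test is conservative: its type-I error at
nominal 0.05 stays at or below 0.05–0.06, which the suite verifies
with 2,000 null replicates of 200 individuals at MAF 0.3.

## Eligibility, best SNP, ranking

A SNP enters meta-analysis when its pooled control MAF exceeds 1% and
at least four independent samples exist. A gene enters the top list
when at least one of its SNPs is significant in the all-stratum or any
single-stratum pooling; the gene is then represented by the SNP with
the smallest all-stratum P (ties by rsID). No multiplicity correction
is applied across meta-analyses, matching the presentation style of
the evidence base being emulated.

## Pathway stage

Annotations are propagated to all `is_a` ancestors (true-path rule),
and each term annotating at least one test gene and two background
genes is tested with the upper-tail hypergeometric probability

$$P = \sum_{i \ge k} \binom{K}{i}\binom{N-K}{n-i} \Big/ \binom{N}{n}.$$

Bonferroni adjustment multiplies by the number of tested terms. Two
gene-count knobs exist because the procedure applies them at different
stages: significance requires adjusted P strictly below 0.003 and at
least **2** test genes; the final report then drops groups shared by
fewer than **3** genes. Raw P values are emitted alongside adjusted
ones so either reading of the significance threshold is inspectable.

Selected terms are remapped to their most specific ancestors in a slim
(high-level) term set; within a slim group, a term whose test-gene set
is a subset of another's collapses into the superset term (ties keep
the term with more background annotations, then the lexically smaller
id) — this is what merges synonymous pairs such as "cell death" and
"regulation of cell death". A packaged blacklist removes nonspecific
terms such as "biological regulation". Only `is_a` edges are
traversed; `part_of` and cross-products are out of scope of the
deliberately minimal OBO dialect, as is any live ontology download.
The three GO namespaces are tested jointly.

## Synthetic data: what it emulates and what it does not

The simulator generates genotype counts — genotypes, not alleles, are
the primitive so that HWE testing on controls is meaningful — for `k`
studies of one SNP. Study log ORs are drawn from
$\mathcal N(\log \theta, \tau^2)$; control genotypes are multinomial
at the control MAF with an optional inbreeding coefficient `F`
distorting Hardy–Weinberg proportions; the case MAF is solved from the
study's OR via $p_a = p e^{\theta_i} / (1 - p + p e^{\theta_i})$ and
case genotypes are always drawn in HWE at $p_a$. Publication
filtering retains study $i$ with probability
$\min(1, e^{-\gamma} + (1 - e^{-\gamma})\,\mathrm{sig}_i)$, where
significance is the study's own 95% CI excluding 1. Publication years
are assigned sequentially from a configurable start year so "first
study" is well defined.

This emulates the *evidence structure* of a curated association
database, not its genesis: there is no linkage disequilibrium between
SNPs, no haplotypes, no covariates, no family-based designs, and the
real database's studies are observational with unknown selection
mechanisms. Passing tests therefore demonstrate that the machinery is
correct under a known generative model, not that the historical
estimates are recoverable — the per-study data behind them were never
archived, which is also why the packaged top-gene table is a
transcription used as a fixture rather than a reproduction target.
Two typographical inconsistencies in that table (the LDLR confidence
bound and the TNF lower bound) are stored as printed and flagged.

The packaged enrichment universe (`synthetic_*` files) is likewise a
constructed stand-in for the historical UniProtKB background: 1,000
filler genes plus the 15 top genes, annotated so that the nine printed
pathway lists emerge from the real enrichment/slim/collapse code path.
It is labelled synthetic in its file names and cannot reproduce the
"146 enriched terms" of a 2010-era ontology release, which would
require that release itself.

## Numerical and design details

* Continuity correction: 0.5 on all four cells, only when a cell is
  zero, flagged in output.
* Degenerate inputs: monomorphic genotype tables give HWE P = 1;
  pooling demands $k \ge 2$ and positive variances; a single remaining
  study in a sensitivity re-pool falls back to its own Wald CI.
* Tie-breaks are always deterministic: rsID order for best-SNP ties,
  background-annotation count then lexical id for collapse ties, gene
  symbol as the final ranking key.
* Determinism: every stochastic routine takes a seed and restores the
  caller's RNG state; identical config + seed give byte-identical
  outputs, and each output file carries the config hash.
* Problem sizes in the test and acceptance suites were chosen to give
  tight Monte-Carlo error at interactive runtimes: 500 replicates for
  parameter recovery (k = 8, 1,000 cases and controls per study,
  OR 1.2, $\tau^2 = 0.05$), 1,000 replicates for null coverage, 200
  for bias-grade calibration, 2,000 for HWE calibration.
* The demonstration pipeline simulates modest heterogeneity
  ($\tau^2 = 0.005$) so that both consistent and heterogeneous
  meta-analyses appear in small demo runs.

## Limitations

The pipeline grades cumulative *allele-contrast* evidence only: no
genotype-model tests, no haplotypes, no meta-regression, no gene-gene
or gene-environment interaction scoring. The bias axis inspects the
four classical checks and cannot see biases that leave the funnel
symmetric and all control groups in equilibrium. Hypergeometric
enrichment inherits the usual caveats of annotation analyses:
background choice matters, annotations are incomplete and correlated,
and a significant term is a shared label, not a mechanism.
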