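Package: credmeta
Title: Credibility-Graded Meta-Analysis of Genetic Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for distilling large collections of candidate-gene
    case-control association studies into a ranked list of credible loci.
    Implements per-SNP allele-contrast odds-ratio estimation with
    Haldane-Anscombe continuity correction, DerSimonian-Laird
    random-effects pooling with Cochran's Q and I-squared heterogeneity,
    HuGENet interim credibility grading (amount of evidence, consistency
    of replication, protection from bias, including an exact
    Hardy-Weinberg equilibrium test, first-study and HWE sensitivity
    re-pooling, and Egger's regression for publication bias), and a
    shared-pathway stage based on hypergeometric Gene Ontology term
    over-representation with Bonferroni adjustment, slim remapping and
    term collapsing.  A synthetic multi-study genotype simulator with
    known ground truth makes the whole pipeline exercisable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    optparse
Config/testthat/edition: 3
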