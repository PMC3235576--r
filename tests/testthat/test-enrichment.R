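chain_dag <- function() {
  new_ontology_dag(
    data.frame(id = c("C:1", "C:2", "C:3"),
               name = c("root", "mid", "leaf"),
               namespace = "biological_process", obsolete = FALSE,
               stringsAsFactors = FALSE),
    list("C:1" = character(0), "C:2" = "C:1", "C:3" = "C:2"))
}

test_that("annotations propagate to every ancestor and the operation is idempotent", {
  dag <- chain_dag()
  ann <- annotation_set(data.frame(gene = "g1", term = "C:3"),
                        universe = c("g1", "g2"))
  prop <- propagate_annotations(ann, dag)
  expect_setequal(prop$pairs$term, c("C:1", "C:2", "C:3"))
  expect_equal(propagate_annotations(prop, dag), prop)
  root_only <- annotation_set(data.frame(gene = "g1", term = "C:1"),
                              universe = "g1")
  expect_equal(propagate_annotations(root_only, dag), root_only)
  expect_error(
    propagate_annotations(
      annotation_set(data.frame(gene = "g1", term = "C:9")), dag),
    "C:9")
})

test_that("propagation equals the transitive closure on a random DAG", {
  set.seed(31)
  n <- 15
  ids <- sprintf("R:%02d", 1:n)
  parents <- list("R:01" = character(0))
  for (i in 2:n) {
    parents[[ids[i]]] <- sample(ids[1:(i - 1)], sample(1:min(2, i - 1), 1))
  }
  dag <- new_ontology_dag(
    data.frame(id = ids, name = ids, namespace = "bp", obsolete = FALSE,
               stringsAsFactors = FALSE), parents)
  # reachability by brute-force repeated edge expansion
  reach <- function(id) {
    out <- parents[[id]]
    repeat {
      grown <- unique(c(out, unlist(parents[out])))
      if (length(grown) == length(out)) return(out)
      out <- grown
    }
  }
  for (id in ids) expect_setequal(term_ancestors(dag, id), reach(id))
  genes <- sprintf("g%d", 1:6)
  ann <- annotation_set(
    data.frame(gene = sample(genes, 10, replace = TRUE),
               term = sample(ids, 10, replace = TRUE)))
  prop <- propagate_annotations(ann, dag)
  for (g in unique(ann$pairs$gene)) {
    direct <- ann$pairs$term[ann$pairs$gene == g]
    expected <- unique(c(direct, unlist(lapply(direct, reach))))
    expect_setequal(prop$pairs$term[prop$pairs$gene == g], expected)
  }
})

test_that("hypergeometric P values match exact enumeration", {
  # published-style worked example: N=20, K=5, n=5, k=3
  dag <- chain_dag()
  genes <- sprintf("u%02d", 1:20)
  ann <- annotation_set(
    rbind(data.frame(gene = genes[1:5], term = "C:3"),
          data.frame(gene = genes, term = "C:1")))
  res <- term_enrichment(genes[1:5], ann, dag)
  row <- res[res$term_id == "C:3", ]
  # draw 5 of 20 with 5 annotated: 3 or more hits
  expect_equal(row$k_test, 3L + 2L)  # first five genes are the test set
  # move to a 3-hit configuration explicitly
  res2 <- term_enrichment(c(genes[1:3], genes[6:7]), ann, dag)
  row2 <- res2[res2$term_id == "C:3", ]
  expect_equal(row2$k_test, 3L)
  expect_equal(row2$p_raw, 1126 / 15504, tolerance = 1e-12)
  expect_equal(row2$p_raw, hyper_oracle(20, 5, 5, 3), tolerance = 1e-12)
  # a term covering the whole universe is never enriched
  expect_equal(res$p_raw[res$term_id == "C:1"], 1)
})

test_that("hypergeometric tail matches enumeration across random small universes", {
  set.seed(41)
  for (i in 1:12) {
    N <- sample(8:25, 1)
    K <- sample(2:(N - 1), 1)
    n <- sample(2:min(6, N - 1), 1)
    genes <- sprintf("x%02d", 1:N)
    dag <- chain_dag()
    ann <- annotation_set(
      rbind(data.frame(gene = genes[1:K], term = "C:3"),
            data.frame(gene = genes, term = "C:1")))
    test_set <- sample(genes, n)
    res <- term_enrichment(test_set, ann, dag)
    row <- res[res$term_id == "C:3", ]
    if (nrow(row)) {
      expect_equal(row$p_raw, hyper_oracle(N, K, n, row$k_test),
                   tolerance = 1e-10)
    }
  }
})

test_that("enrichment P decreases as the test-set overlap grows", {
  dag <- chain_dag()
  genes <- sprintf("m%02d", 1:30)
  ann <- annotation_set(
    rbind(data.frame(gene = genes[1:8], term = "C:3"),
          data.frame(gene = genes, term = "C:1")))
  ps <- vapply(1:5, function(k) {
    test_set <- c(genes[1:k], genes[9:(14 - k)])
    res <- term_enrichment(test_set, ann, dag)
    res$p_raw[res$term_id == "C:3"]
  }, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("test genes outside the universe are rejected", {
  dag <- chain_dag()
  ann <- annotation_set(data.frame(gene = "g1", term = "C:1"))
  expect_error(term_enrichment("stranger", ann, dag), "stranger")
})

test_that("significance filter applies strict alpha and the gene minimum", {
  res <- data.frame(term_id = c("a", "b", "c"), term_name = c("a", "b", "c"),
                    k_test = c(1L, 3L, 3L), K_background = c(5L, 5L, 5L),
                    n_test = 5L, N_background = 100L,
                    p_raw = c(1e-5, 1e-3, 3e-3),
                    p_bonferroni = c(3e-5, 3e-3, 9e-3),
                    stringsAsFactors = FALSE)
  kept <- select_significant(res, alpha = 0.003, min_genes = 2)
  expect_equal(kept$term_id, character(0))  # 1-gene term and boundary out
  kept2 <- select_significant(res, alpha = 0.0031, min_genes = 2)
  expect_equal(kept2$term_id, "b")
})

test_that("slim remapping returns the most specific slim ancestors", {
  dag <- chain_dag()
  expect_equal(slim_remap("C:2", dag, c("C:2", "C:1")), "C:2")  # identity
  expect_equal(slim_remap("C:3", dag, c("C:2", "C:1")), "C:2")  # nearest
  expect_length(slim_remap("C:1", dag, "C:2"), 0)  # nothing above root
  # diamond: two slim ancestors on disjoint paths are both kept
  dia <- new_ontology_dag(
    data.frame(id = c("D:0", "D:1", "D:2", "D:3"),
               name = c("top", "left", "right", "bottom"),
               namespace = "bp", obsolete = FALSE, stringsAsFactors = FALSE),
    list("D:0" = character(0), "D:1" = "D:0", "D:2" = "D:0",
         "D:3" = c("D:1", "D:2")))
  expect_setequal(slim_remap("D:3", dia, c("D:1", "D:2", "D:0")),
                  c("D:1", "D:2"))
})

test_that("slim remapping ignores non-slim intermediates inserted in the path", {
  base <- new_ontology_dag(
    data.frame(id = c("S:1", "S:2"), name = c("slim root", "leaf"),
               namespace = "bp", obsolete = FALSE, stringsAsFactors = FALSE),
    list("S:1" = character(0), "S:2" = "S:1"))
  with_mid <- new_ontology_dag(
    data.frame(id = c("S:1", "S:9", "S:2"),
               name = c("slim root", "intermediate", "leaf"),
               namespace = "bp", obsolete = FALSE, stringsAsFactors = FALSE),
    list("S:1" = character(0), "S:9" = "S:1", "S:2" = "S:9"))
  expect_equal(slim_remap("S:2", base, "S:1"),
               slim_remap("S:2", with_mid, "S:1"))
})

test_that("synonymous terms collapse and small groups are dropped in the report", {
  ids <- c("E:0", "E:1", "E:2", "E:3")
  dag <- new_ontology_dag(
    data.frame(id = ids,
               name = c("root", "cell death", "regulation of cell death",
                        "tiny process"),
               namespace = "bp", obsolete = FALSE, stringsAsFactors = FALSE),
    list("E:0" = character(0), "E:1" = "E:0", "E:2" = "E:1",
         "E:3" = "E:0"))
  genes <- sprintf("z%02d", 1:40)
  test_set <- genes[1:6]
  ann <- annotation_set(rbind(
    data.frame(gene = genes[1:3], term = "E:1"),
    data.frame(gene = genes[7], term = "E:1"),   # extra background
    data.frame(gene = genes[8], term = "E:1"),
    data.frame(gene = genes[1:3], term = "E:2"),
    data.frame(gene = genes[9], term = "E:2"),
    data.frame(gene = genes[4:5], term = "E:3"),
    data.frame(gene = genes, term = "E:0")))
  enr <- term_enrichment(test_set, ann, dag)
  rep <- collapse_and_report(enr, dag, ann, test_set,
                             slim_terms = c("E:1", "E:3"),
                             min_report_genes = 3,
                             blacklist = "root")
  # regulation term collapses into cell death (equal gene sets, more
  # background annotations on the parent); the 2-gene group is dropped
  expect_equal(rep$term_id, "E:1")
  expect_equal(rep$absorbed, "E:2")
  expect_equal(rep$genes, paste(genes[1:3], collapse = ","))
  rep2 <- collapse_and_report(enr, dag, ann, test_set,
                              slim_terms = c("E:1", "E:3"),
                              min_report_genes = 2, blacklist = "root")
  expect_setequal(rep2$term_id, c("E:1", "E:3"))
})
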