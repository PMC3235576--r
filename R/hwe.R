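#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on a genotype triple (hom minor, het, hom
#' major).  Conditional on the observed allele counts, the probability of
#' each admissible heterozygote count (same parity as the observed rare
#' allele count) follows the Levene-Haldane distribution
#' \deqn{P(h) = \frac{n!\, n_r!\, (2n-n_r)!\, 2^h}
#'   {(2n)!\, h!\, ((n_r-h)/2)!\, ((2n-n_r-h)/2)!}}
#' where n is the number of individuals and n_r the rarer allele count.
#' The P value sums the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count, so
#' it always lies in (0, 1] and the test is conservative.
#'
#' @param hom_minor,het,hom_major Non-negative genotype counts.
#' @return Exact two-sided P value.
#' @examples
#' hwe_exact_test(25, 50, 25)  # conditional mode: P = 1
#' hwe_exact_test(5, 10, 85)
#' @export
hwe_exact_test <- function(hom_minor, het, hom_major) {
  counts <- c(hom_minor, het, hom_major)
  if (length(counts) != 3L || anyNA(counts) || any(counts < 0)) {
    stop("genotype counts must be three non-negative numbers",
         call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("total genotype count must be positive", call. = FALSE)
  n_minor <- 2 * hom_minor + het
  n_rare <- min(n_minor, 2 * n - n_minor)
  if (n_rare == 0) return(1)  # monomorphic: single possible table
  h_values <- seq.int(n_rare %% 2, n_rare, by = 2L)
  # restrict to tables whose implied major homozygote count is feasible
  h_values <- h_values[(2 * n - n_rare - h_values) >= 0 &
                         (2 * n - n_rare - h_values) %% 2 == 0]
  log_p <- lgamma(n + 1) - lgamma((n_rare - h_values) / 2 + 1) -
    lgamma(h_values + 1) - lgamma((2 * n - n_rare - h_values) / 2 + 1) +
    h_values * log(2) +
    lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) - lgamma(2 * n + 1)
  probs <- exp(log_p - max(log_p))
  probs <- probs / sum(probs)
  p_obs <- probs[match(het, h_values)]
  if (is.na(p_obs)) {
    stop("observed heterozygote count is inconsistent with allele counts",
         call. = FALSE)
  }
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}
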