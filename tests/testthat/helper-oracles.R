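# Independent oracles, deliberately written as plain transcriptions of
# the defining formulas (loops, no shared code with the package).

# Random-effects pooling by direct formula evaluation.
dl_oracle <- function(y, v) {
  k <- length(y)
  w <- numeric(k)
  for (i in seq_len(k)) w[i] <- 1 / v[i]
  yfe <- sum(w * y) / sum(w)
  q <- 0
  for (i in seq_len(k)) q <- q + w[i] * (y[i] - yfe)^2
  denom <- sum(w) - sum(w^2) / sum(w)
  t2 <- (q - (k - 1)) / denom
  if (t2 < 0) t2 <- 0
  ws <- numeric(k)
  for (i in seq_len(k)) ws[i] <- 1 / (v[i] + t2)
  est <- sum(ws * y) / sum(ws)
  se <- sqrt(1 / sum(ws))
  list(or = exp(est), lo = exp(est - 1.96 * se), hi = exp(est + 1.96 * se),
       p = 2 * pnorm(-abs(est / se)), q = q, tau2 = t2,
       i2 = if (q == 0) 0 else max(0, (q - (k - 1)) / q) * 100)
}

# Exact HWE p-value by enumerating every genotype triple compatible with
# the margins.
hwe_oracle <- function(hom_minor, het, hom_major) {
  n <- hom_minor + het + hom_major
  n_minor <- 2 * hom_minor + het
  tables <- list()
  for (i in 0:n) {
    j <- n_minor - 2 * i
    if (j >= 0 && n - i - j >= 0) tables[[length(tables) + 1]] <- c(i, j)
  }
  weight <- vapply(tables, function(t) {
    i <- t[1]; j <- t[2]; k <- n - i - j
    exp(lgamma(n + 1) - lgamma(i + 1) - lgamma(j + 1) - lgamma(k + 1) +
          j * log(2))
  }, 0)
  probs <- weight / sum(weight)
  obs <- which(vapply(tables, function(t) t[1] == hom_minor &&
                        t[2] == het, NA))
  sum(probs[probs <= probs[obs] * (1 + 1e-12)])
}

# Upper-tail hypergeometric probability by full enumeration of all draws
# of size n from a universe of N genes of which the first K are annotated.
hyper_oracle <- function(N, K, n, k) {
  draws <- combn(N, n)
  mean(colSums(draws <= K) >= k)
}
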