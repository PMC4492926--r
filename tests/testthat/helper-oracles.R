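# Independent oracles used across the suite. These deliberately take the
# counting / brute-force route rather than the odds-form algebra the
# package implements, so the two derivations check each other.

# Posterior probability of disease after a positive result by exact
# frequency enumeration over an n-patient cohort.
oracle_posterior_positive <- function(pretest, sens, spec, n = 1e6) {
  tp <- n * pretest * sens
  fp <- n * (1 - pretest) * (1 - spec)
  tp / (tp + fp)
}

# Optimal 2-cell integer split of `total` with first-cell target `t1`:
# brute force over all candidates, minimising |count - target|, ties to
# the larger first cell (the stable largest-remainder tie rule).
oracle_split2 <- function(t1, total) {
  cand <- 0:total
  err <- abs(cand - t1)
  max(cand[abs(err - min(err)) < 1e-9])
}

# Pearson chi-squared statistic as an explicit double sum.
oracle_chisq_stat <- function(tab) {
  n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  stat
}

vignette_accuracy <- function() test_accuracy(0.60, 0.90)
quiz_accuracy <- function() test_accuracy(0.90, 0.50)

# Published per-arm OR/CI values (2 dp) used by the regression suite.
printed_or_values <- function() {
  data.frame(
    outcome = rep(c("treat", "correct"), each = 3),
    arm = rep(c("nomogram", "pmp", "nft"), 2),
    or = c(1.09, 1.49, 1.43, 2.60, 4.98, 4.09),
    lo = c(0.75, 1.02, 0.98, 1.58, 3.12, 2.54),
    hi = c(1.58, 2.16, 2.08, 4.29, 7.95, 6.58))
}
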