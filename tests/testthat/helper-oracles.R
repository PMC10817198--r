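# Independent oracles used to cross-check the closed-form implementation.
# These deliberately avoid the code paths they verify.

# Empirical Gini by the sorted-rank formula, plus a block-resampled Monte
# Carlo standard error (the pairwise-difference definition is O(n^2) and is
# used only at small n below).
mc_gini <- function(y, blocks = 10L) {
  gini_of <- function(x) {
    x <- sort(x)
    n <- length(x)
    (2 * sum(seq_len(n) * x)) / (n * sum(x)) - (n + 1) / n
  }
  per_block <- vapply(split(y, rep(seq_len(blocks), length.out = length(y))),
                      gini_of, numeric(1))
  c(est = mean(per_block), se = stats::sd(per_block) / sqrt(blocks))
}

# Pairwise-difference Gini (the definition), feasible only for small n.
pairwise_gini <- function(y) {
  mean(abs(outer(y, y, "-"))) / (2 * mean(y))
}

# Grid-search inversion of the gamma Gini identity, independent of the
# package bisection: coarse log-spaced scan over [1e-3, 1e3], then linear
# refinement at 1e-6 resolution around the best coarse point.
grid_invert_gini <- function(gini) {
  s2g <- function(a) exp(lgamma(a + 0.5) - lgamma(a + 1) - 0.5 * log(pi))
  coarse <- exp(seq(log(1e-3), log(1e3), length.out = 100001))
  i <- which.min(abs(s2g(coarse) - gini))
  fine <- seq(coarse[max(1, i - 1)], coarse[min(length(coarse), i + 1)],
              by = 1e-6)
  fine[which.min(abs(s2g(fine) - gini))]
}

# Proportion-type Monte Carlo estimate with binomial standard error.
mc_proportion <- function(hits) {
  p <- mean(hits)
  c(est = p, se = sqrt(max(p * (1 - p), 1e-12) / length(hits)))
}

# Mean-type Monte Carlo estimate with standard error.
mc_mean <- function(x) {
  c(est = mean(x), se = stats::sd(x) / sqrt(length(x)))
}

# A tiny well-formed country table used across io / engine tests.
fixture_countries <- function() {
  data.frame(
    iso3 = c("AAA", "BBB", "CCC"),
    name = c("Alpha", "Beta", "Gamma"),
    income_group = c("LIC", "LMIC", "HIC"),
    who_region = c("AFR", "SEAR", "EUR"),
    population = c(3e7, 8e7, 1e7),
    gini = c(0.45, 0.38, 0.30),
    hepc = c(600, 1800, 22000),
    gdp_pc = c(900, 3000, 45000),
    oop_share = c(0.50, 0.40, 0.15),
    pov_headcount_190 = c(0.60, 0.20, 0.001),
    pov_headcount_320 = c(0.85, 0.45, 0.004),
    pov_gap_215 = c(0.35, 0.10, 0.0005),
    pct_urban = c(0.35, 0.5, 0.8),
    data_year = 2020L,
    stringsAsFactors = FALSE
  )
}
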