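test_that("replicate poverty statistics agree with the closed forms", {
  m <- income_model(1400, 0.43)
  line <- 365 * 1.90
  got <- replicate_poverty_stats(m, line, reps = 25, draws_per_rep = 1e4,
                                 seed = 61)
  n_total <- 25 * 1e4
  hc <- poverty_headcount(m, line)
  se_hc <- sqrt(hc * (1 - hc) / n_total)
  expect_lt(abs(got["headcount"] - hc), 3 * se_hc)
  # gap SE from a direct sample of the shortfall variable
  y <- sample_incomes(m, 1e5, seed = 62)
  short <- pmax(0, (line - y) / line)
  se_gap <- stats::sd(short) / sqrt(n_total)
  expect_lt(abs(got["gap"] - poverty_gap(m, line)), 3 * se_gap)

  # determinism and convergence with draws_per_rep
  expect_identical(got, replicate_poverty_stats(m, line, 25, 1e4, seed = 61))
  coarse <- replicate_poverty_stats(m, line, 25, 1e3, seed = 63)
  fine <- replicate_poverty_stats(m, line, 25, 1e5, seed = 63)
  expect_lt(abs(fine["headcount"] - hc), abs(coarse["headcount"] - hc) + 1e-3)
  expect_lt(abs(fine["gap"] - poverty_gap(m, line)), 2e-3)
})

test_that("calibration selects the candidate matching the observed headcount", {
  line <- 365 * 1.90
  truth <- income_model(900, 0.47)
  cand <- seq(300, 2100, by = 100)
  res <- calibrate_mean(poverty_headcount(truth, line),
                        poverty_gap(truth, line), line, 0.47, cand)
  expect_equal(res$chosen_mean, 900)       # truth on the grid: exact
  expect_equal(res$residual, 0, tolerance = 1e-12)

  # truth off the grid: exhaustive evaluation says the nearest achievable
  # headcount wins
  truth2 <- income_model(955, 0.47)
  obs_hc <- poverty_headcount(truth2, line)
  res2 <- calibrate_mean(obs_hc, poverty_gap(truth2, line), line, 0.47, cand)
  errs <- vapply(cand, function(m) {
    abs(poverty_headcount(income_model(m, 0.47), line) - obs_hc)
  }, numeric(1))
  expect_equal(res2$chosen_mean, cand[which.min(errs)])
  expect_lte(abs(res2$chosen_mean - 955), 100)  # within one grid step

  # zero observed headcount: the largest candidate has the lowest headcount
  res3 <- calibrate_mean(0, 0, line, 0.47, cand)
  expect_equal(res3$chosen_mean, max(cand))
  expect_error(calibrate_mean(0.5, 0.2, line, 0.47, numeric(0)),
               class = "cherisk_usage_error")
})

test_that("proxy choice minimizes the combined poverty-statistic residual", {
  line_hc <- 365 * 1.90
  line_gap <- 365 * 2.15
  grid <- calibration_grid()

  # stats generated from the HEpc model: HEpc wins with zero-ish residual
  hep <- 700; gini <- 0.46
  m <- income_model(hep, gini)
  country <- list(iso3 = "TST", gini = gini, hepc = hep, gdp_pc = 2.0 * hep,
                  pov_headcount_190 = poverty_headcount(m, line_hc),
                  pov_gap_215 = poverty_gap(m, line_gap))
  res <- choose_proxy(country, grid)
  expect_equal(res$proxy[res$selected], "hepc")
  expect_equal(res$chosen_mean[res$selected], hep, tolerance = 1e-9)
  expect_lte(res$residual[res$selected],
             min(res$residual[!res$selected]))

  # stats generated from 0.6 x GDPpc: the GDPpc grid covers it and wins
  gdp <- 3000
  m2 <- income_model(0.6 * gdp, gini)
  country2 <- list(iso3 = "TS2", gini = gini, hepc = 3.1 * gdp, gdp_pc = gdp,
                   pov_headcount_190 = poverty_headcount(m2, line_hc),
                   pov_gap_215 = poverty_gap(m2, line_gap))
  res2 <- choose_proxy(country2, grid)
  expect_equal(res2$proxy[res2$selected], "gdp_pc")
  # exhaustive recomputation of both residuals agrees with the choice
  best_res <- vapply(c("hepc", "gdp_pc"), function(p) {
    base <- if (p == "hepc") country2$hepc else country2$gdp_pc
    r <- calibrate_mean(country2$pov_headcount_190, country2$pov_gap_215,
                        line_hc, gini, grid$multipliers * base,
                        gap_line = line_gap)
    r$residual
  }, numeric(1))
  expect_equal(unname(which.min(best_res)), which(res2$selected))

  # missing gap: headcount-only calibration with a warning
  expect_warning(
    calibrate_mean(country$pov_headcount_190, NA, line_hc, gini,
                   grid$multipliers * hep, gap_line = line_gap),
    "headcount alone")
  country3 <- country
  country3$pov_gap_215 <- NULL
  res3 <- suppressWarnings(choose_proxy(country3, grid))
  expect_equal(res3$chosen_mean[res3$selected], hep, tolerance = 1e-9)
})

test_that("calibration recovers generating means across synthetic countries", {
  syn <- generate_countries(synthetic_config(
    n_per_group = c(LIC = 15L, LMIC = 15L, UMIC = 10L, HIC = 10L),
    seed = 71, noise_sd = 0))
  grid <- calibration_grid()
  line_hc <- 365 * 1.90
  line_gap <- 365 * 2.15
  hit <- vapply(seq_len(nrow(syn$countries)), function(i) {
    ci <- syn$countries[i, ]
    res <- calibrate_mean(ci$pov_headcount_190, ci$pov_gap_215, line_hc,
                          ci$gini, grid$multipliers * ci$hepc,
                          gap_line = line_gap)
    abs(log(res$chosen_mean / syn$ground_truth$mean[i]))
  }, numeric(1))
  step <- log(grid$multipliers[2] / grid$multipliers[1])
  # noise-free with truth on the grid: recovery within one grid step always
  expect_true(all(hit <= step * (1 + 1e-9)))
})
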