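make_cells <- function(countries, spec = scenario_spec()) {
  out <- do.call(rbind, lapply(seq_len(nrow(countries)), function(i) {
    country_risk_profile(countries[i, ], spec = spec)
  }))
  rownames(out) <- NULL
  out
}

test_that("group means and SEMs follow the documented formulas", {
  countries <- fixture_countries()
  countries$income_group <- c("LIC", "LIC", "HIC")
  cells <- make_cells(countries)
  summ <- suppressMessages(
    group_summaries(cells, countries, grouping = "wb_income"))

  # one-country group: mean is that country's risk, SEM 0
  hic <- summ[summ$group == "HIC" & summ$quintile == "poorest" &
                summ$scenario == "baseline", ]
  own <- cells$risk[cells$iso3 == "CCC" & cells$quintile == "poorest" &
                      cells$scenario == "baseline"]
  expect_equal(hic$mean_risk, own)
  expect_identical(hic$sem_risk, 0)
  expect_identical(hic$n_countries, 1L)

  # two-point group: mean and SD/sqrt(2) recomputed independently
  lic <- summ[summ$group == "LIC" & summ$quintile == "poor" &
                summ$scenario == "50%", ]
  vals <- cells$risk[cells$iso3 %in% c("AAA", "BBB") &
                       cells$quintile == "poor" & cells$scenario == "50%"]
  expect_equal(lic$mean_risk, mean(vals), tolerance = 1e-12)
  expect_equal(lic$sem_risk, stats::sd(vals) / sqrt(2), tolerance = 1e-12)

  # two synthetic risks 0.1 and 0.3: mean 0.2, SEM 0.1
  toy_cells <- data.frame(iso3 = c("AAA", "BBB"), quintile = "poorest",
                          scenario = "baseline", risk = c(0.1, 0.3),
                          protected = NA_real_)
  toy <- suppressMessages(
    group_summaries(toy_cells, countries, grouping = "wb_income"))
  expect_equal(toy$mean_risk, 0.2)
  expect_equal(toy$sem_risk, 0.1, tolerance = 1e-12)
})

test_that("equal-weight summaries match a brute-force recomputation", {
  syn <- generate_countries(synthetic_config(
    n_per_group = c(LIC = 4L, LMIC = 4L, UMIC = 4L, HIC = 4L), seed = 81))
  cells <- make_cells(syn$countries)
  summ <- suppressMessages(
    group_summaries(cells, syn$countries, grouping = "who_region"))
  lookup <- stats::setNames(as.character(syn$countries$who_region),
                            syn$countries$iso3)
  for (r in sample(nrow(summ), 25)) {
    row <- summ[r, ]
    vals <- cells$risk[lookup[cells$iso3] == row$group &
                         cells$quintile == row$quintile &
                         cells$scenario == row$scenario]
    expect_equal(row$mean_risk, mean(vals), tolerance = 1e-12)
    expect_equal(row$n_countries, length(vals))
  }
})

test_that("aggregation linearity identities hold", {
  syn <- generate_countries(synthetic_config(
    n_per_group = c(LIC = 5L, LMIC = 5L, UMIC = 0L, HIC = 5L), seed = 82))
  cells <- make_cells(syn$countries)
  summ <- suppressMessages(
    group_summaries(cells, syn$countries, grouping = "wb_income"))

  for (g in unique(summ$group)) {
    for (s in unique(summ$scenario)) {
      sub <- summ[summ$group == g & summ$scenario == s, ]
      # group mean of overall cells = mean of group's per-quintile means
      expect_equal(sub$mean_risk[sub$quintile == "overall"],
                   mean(sub$mean_risk[sub$quintile != "overall"]),
                   tolerance = 1e-12)
      # mean protection = baseline mean risk - scenario mean risk
      if (s != "baseline") {
        base <- summ[summ$group == g & summ$scenario == "baseline", ]
        expect_equal(sub$mean_protected,
                     base$mean_risk[match(sub$quintile, base$quintile)] -
                       sub$mean_risk,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("population weighting with equal populations equals equal weighting", {
  countries <- fixture_countries()
  countries$population <- rep(5e7, 3)
  cells <- make_cells(countries)
  eq <- suppressMessages(group_summaries(cells, countries, "who_region",
                                         weighting = "equal"))
  pw <- suppressMessages(group_summaries(cells, countries, "who_region",
                                         weighting = "population"))
  expect_equal(pw$mean_risk, eq$mean_risk, tolerance = 1e-12)
  expect_equal(pw$sem_risk, eq$sem_risk, tolerance = 1e-12)
})

test_that("equity gap is the poorest-richest difference in percentage points", {
  summ <- data.frame(
    group = "LIC", scenario = "baseline",
    quintile = c("poorest", "poor", "middle", "rich", "richest"),
    mean_risk = c(0.195, 0.09, 0.05, 0.03, 0.021)
  )
  expect_equal(equity_gap(summ, "LIC", "baseline"), 17.4, tolerance = 1e-9)
  summ$mean_risk <- rep(0.08, 5)
  expect_equal(equity_gap(summ, "LIC", "baseline"), 0)
  expect_error(equity_gap(summ, "HIC", "baseline"),
               class = "cherisk_usage_error")
})

test_that("unknown group labels are reported with offending countries", {
  countries <- fixture_countries()
  cells <- make_cells(countries)
  cells$iso3[1] <- "ZZZ"
  expect_error(group_summaries(cells, countries, "wb_income"), "ZZZ",
               class = "cherisk_usage_error")
})
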