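#' Configuration for the synthetic country-table generator
#'
#' Defines per-income-group sampling ranges for the indicators the pipeline
#' consumes. Defaults emulate the broad magnitudes seen across World Bank
#' income groups: Gini 0.30-0.55 (LIC/LMIC), 0.30-0.50 (UMIC), 0.25-0.45
#' (HIC); household expenditure per capita 300-900 (LIC), 800-3000 (LMIC),
#' 2500-9000 (UMIC), 8000-40000 (HIC) USD/yr; OOP shares 0.30-0.60
#' (LIC/LMIC), 0.20-0.45 (UMIC), 0.10-0.25 (HIC). These are exercising
#' fixtures with known ground truth, not estimates of any real country.
#'
#' @param n_per_group named integer vector: countries per income group.
#' @param seed mandatory integer seed.
#' @param gini_range,hepc_range,oop_range named lists of `c(lo, hi)` per
#'   income group.
#' @param gdp_ratio_range range of the GDPpc/HEpc ratio (household
#'   consumption is typically 45-75% of GDP).
#' @param population_range range of population sizes (sampled log-uniformly).
#' @param poverty_lines USD/day lines at which observed statistics are
#'   generated: headcounts at the first two, FGT-1 gap at the third.
#' @param noise_sd standard deviation of the observation noise added to the
#'   closed-form poverty statistics (fraction scale); noise is truncated at
#'   +/- 3 sd and results are clipped to \[0, 1\].
#' @return an object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(
    n_per_group = c(LIC = 10L, LMIC = 10L, UMIC = 10L, HIC = 10L),
    seed,
    gini_range = list(LIC = c(0.30, 0.55), LMIC = c(0.30, 0.55),
                      UMIC = c(0.30, 0.50), HIC = c(0.25, 0.45)),
    hepc_range = list(LIC = c(300, 900), LMIC = c(800, 3000),
                      UMIC = c(2500, 9000), HIC = c(8000, 40000)),
    oop_range = list(LIC = c(0.30, 0.60), LMIC = c(0.30, 0.60),
                     UMIC = c(0.20, 0.45), HIC = c(0.10, 0.25)),
    gdp_ratio_range = c(1.3, 2.2),
    population_range = c(1e6, 2e8),
    poverty_lines = c(1.90, 3.20, 2.15),
    noise_sd = 0.01) {
  if (missing(seed)) stop_usage("`seed` is mandatory for synthetic generation")
  groups <- names(n_per_group)
  if (is.null(groups) || !all(groups %in% c("LIC", "LMIC", "UMIC", "HIC"))) {
    stop_usage("`n_per_group` must be named with income groups LIC/LMIC/UMIC/HIC")
  }
  check_range <- function(r, lo_ok, hi_ok, what) {
    bad <- vapply(r, function(x) {
      length(x) != 2L || x[1] >= x[2] || x[1] < lo_ok || x[2] > hi_ok
    }, logical(1))
    if (any(bad)) stop_usage("invalid ", what, " range for group(s): ",
                             paste(names(r)[bad], collapse = ", "))
  }
  check_range(gini_range[groups], 0.01, 0.99, "gini")
  check_range(hepc_range[groups], 0, Inf, "hepc")
  check_range(oop_range[groups], 0, 1, "oop_share")
  if (noise_sd < 0) stop_usage("`noise_sd` must be non-negative")
  structure(
    list(n_per_group = n_per_group, seed = seed, gini_range = gini_range,
         hepc_range = hepc_range, oop_range = oop_range,
         gdp_ratio_range = gdp_ratio_range,
         population_range = population_range,
         poverty_lines = poverty_lines, noise_sd = noise_sd),
    class = "synthetic_config"
  )
}

#' Generate a synthetic country table with known ground truth
#'
#' Samples country indicators uniformly within the configured per-group
#' ranges and derives each country's observed poverty statistics from its
#' generating gamma income model: headcounts at the first two poverty lines
#' and the FGT-1 gap at the third, all closed-form values perturbed by
#' truncated Gaussian noise (sd `noise_sd`, truncated at 3 sd, clipped to
#' \[0, 1\]; the two headcounts are re-ordered if noise inverts them so the
#' higher line always dominates). The generating mean/shape/scale per country
#' are returned alongside, so calibration and pipeline recovery can be
#' checked against truth. Deterministic given the configured seed.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `"synthetic_countries"`: list with `countries`
#'   (a country table as documented in [read_country_table()]) and
#'   `ground_truth` (`iso3`, `mean`, `shape`, `scale`).
#' @export
generate_countries <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  groups <- names(config$n_per_group)
  regions <- c("AFR", "AMR", "EMR", "EUR", "SEAR", "WPR")

  with_seed(config$seed, {
    rows <- list(); truth <- list(); k <- 0L
    for (g in groups) {
      n <- config$n_per_group[[g]]
      if (n < 1L) next
      for (i in seq_len(n)) {
        k <- k + 1L
        gini <- stats::runif(1, config$gini_range[[g]][1],
                             config$gini_range[[g]][2])
        hepc <- stats::runif(1, config$hepc_range[[g]][1],
                             config$hepc_range[[g]][2])
        oop <- stats::runif(1, config$oop_range[[g]][1],
                            config$oop_range[[g]][2])
        gdp <- hepc * stats::runif(1, config$gdp_ratio_range[1],
                                   config$gdp_ratio_range[2])
        pop <- exp(stats::runif(1, log(config$population_range[1]),
                                log(config$population_range[2])))
        model <- income_model(hepc, gini)
        lines_yr <- 365 * config$poverty_lines
        hc1 <- poverty_headcount(model, lines_yr[1])
        hc2 <- poverty_headcount(model, lines_yr[2])
        gap <- poverty_gap(model, lines_yr[3])

        perturb <- function(x) {
          eps <- stats::rnorm(1, 0, config$noise_sd)
          eps <- max(-3 * config$noise_sd, min(3 * config$noise_sd, eps))
          max(0, min(1, x + eps))
        }
        obs1 <- perturb(hc1); obs2 <- perturb(hc2); obs_gap <- perturb(gap)
        if (obs2 < obs1) obs2 <- obs1  # higher line dominates

        iso <- sprintf("X%s%s", LETTERS[(k - 1L) %/% 26L + 1L],
                       LETTERS[(k - 1L) %% 26L + 1L])
        rows[[k]] <- data.frame(
          iso3 = iso,
          name = sprintf("Synthetic country %d", k),
          income_group = g,
          who_region = sample(regions, 1L),
          population = round(pop),
          gini = gini, hepc = hepc, gdp_pc = gdp, oop_share = oop,
          pov_headcount_190 = obs1, pov_headcount_320 = obs2,
          pov_gap_215 = obs_gap,
          pct_urban = stats::runif(1, 0.2, 0.9),
          data_year = 2020L
        )
        truth[[k]] <- data.frame(iso3 = iso, mean = hepc,
                                 shape = model$shape, scale = model$scale)
      }
    }
    structure(
      list(countries = do.call(rbind, rows),
           ground_truth = do.call(rbind, truth),
           config = config),
      class = "synthetic_countries"
    )
  })
}

#' @export
print.synthetic_countries <- function(x, ...) {
  tab <- table(x$countries$income_group)
  cat(sprintf("Synthetic country set: %d countries (%s), seed %d\n",
              nrow(x$countries),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              x$config$seed))
  invisible(x)
}
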