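#' Scenario specification for OOP-reduction analysis
#'
#' Bundles the unit cost of a pediatric surgical procedure, the catastrophic
#' expenditure threshold, and the ladder of out-of-pocket multipliers. The
#' default scenarios keep the household paying 100% (baseline), 70%, 50%,
#' 30% and 10% of its baseline OOP payment.
#'
#' @param cost unit cost of the procedure, USD (default 200).
#' @param threshold catastrophic threshold as a fraction of annual income
#'   (default 0.10).
#' @param multipliers OOP multipliers in (0, 1\], baseline 1.0 first.
#' @return an object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(cost = 200, threshold = 0.10,
                          multipliers = c(1.0, 0.7, 0.5, 0.3, 0.1)) {
  if (!is.numeric(cost) || length(cost) != 1L || !is.finite(cost) || cost < 0) {
    stop_domain("`cost` must be a non-negative number")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop_domain("`threshold` must lie in (0, 1]")
  }
  if (!is.numeric(multipliers) || length(multipliers) < 1L ||
      any(multipliers <= 0) || any(multipliers > 1) || multipliers[1] != 1) {
    stop_domain("`multipliers` must lie in (0, 1] with the baseline 1.0 first")
  }
  labels <- ifelse(multipliers == 1, "baseline",
                   paste0(round(100 * multipliers), "%"))
  structure(
    list(cost = cost, threshold = threshold, multipliers = multipliers,
         labels = labels),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario spec: cost $%.0f, CHE threshold %.0f%%, scenarios %s\n",
              x$cost, 100 * x$threshold, paste(x$labels, collapse = "/")))
  invisible(x)
}

#' Risk of catastrophic health expenditure
#'
#' A household incurs CHE when its OOP payment reaches the threshold share of
#' its income, `oop_paid >= threshold * y`. Under the gamma income law the
#' population risk is the distribution's cumulative probability at
#' `oop_paid / threshold` — the regularized lower incomplete gamma integral
#' of the income density up to that point.
#'
#' @param model a `gamma_income` object.
#' @param oop_paid out-of-pocket payment, USD; non-negative. Vectorized.
#' @param threshold catastrophic threshold as a fraction of income; positive.
#' @return CHE risk in \[0, 1\].
#' @export
#' @examples
#' m <- income_model(1000, 0.5)
#' che_risk(m, 100, 0.1)  # 1 - exp(-1): exponential closed form
che_risk <- function(model, oop_paid, threshold) {
  stopifnot(inherits(model, "gamma_income"))
  if (!is.numeric(oop_paid) || any(!is.finite(oop_paid)) || any(oop_paid < 0)) {
    stop_domain("`oop_paid` must be non-negative and finite")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop_domain("`threshold` must be positive")
  }
  stats::pgamma(oop_paid / threshold, shape = model$shape, scale = model$scale)
}

#' Household OOP payment under a reduction scenario
#'
#' The baseline payment is the country's OOP share of the procedure cost;
#' a scenario multiplies that payment by its OOP multiplier.
#'
#' @param baseline_share country OOP share of health expenditure, in \[0, 1\].
#' @param multiplier scenario multiplier in \[0, 1\].
#' @param cost procedure cost, USD.
#' @return the OOP payment in USD: `multiplier * baseline_share * cost`.
#' @export
scenario_oop <- function(baseline_share, multiplier, cost) {
  if (any(c(baseline_share, multiplier, cost) < 0) ||
      any(baseline_share > 1) || any(multiplier > 1)) {
    stop_domain("shares and multipliers must lie in [0, 1]; cost must be >= 0")
  }
  multiplier * baseline_share * cost
}

#' Population protected from CHE by an OOP reduction
#'
#' @param baseline_risk CHE risk at baseline, in \[0, 1\].
#' @param scenario_risk CHE risk under the reduction scenario, in \[0, 1\].
#' @return the protected fraction, `baseline_risk - scenario_risk`.
#' @export
protection <- function(baseline_risk, scenario_risk) {
  if (any(baseline_risk < 0) || any(baseline_risk > 1) ||
      any(scenario_risk < 0) || any(scenario_risk > 1)) {
    stop_domain("risks must lie in [0, 1]")
  }
  baseline_risk - scenario_risk
}

#' Per-country CHE risk profile across quintiles and scenarios
#'
#' Builds the five quintile income distributions from the country's household
#' expenditure per capita and Gini index, then evaluates the CHE risk of the
#' scenario OOP payment for each quintile under every multiplier. An
#' "overall" row per scenario carries the unweighted mean of the five
#' quintile risks; `protected` is the baseline risk minus the scenario risk
#' (NA at baseline); `expected_count` multiplies the risk by the quintile's
#' population share (population/5, or the full population for "overall").
#'
#' @param country one-row data frame (or list) with fields `iso3`,
#'   `population`, `gini`, `hepc`, `oop_share` (see [read_country_table()]
#'   for the full column contract).
#' @param spec a [scenario_spec()].
#' @param pegs quintile mean multipliers passed to [quintile_models()].
#' @return a data frame of risk cells with columns `iso3`, `quintile`
#'   (poorest/poor/middle/rich/richest/overall), `scenario`, `multiplier`,
#'   `oop_paid`, `risk`, `protected`, `expected_count`.
#' @export
country_risk_profile <- function(country, spec = scenario_spec(),
                                 pegs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  stopifnot(inherits(spec, "scenario_spec"))
  country <- as.list(country)
  for (f in c("iso3", "population", "gini", "hepc", "oop_share")) {
    if (is.null(country[[f]]) || length(country[[f]]) != 1L ||
        is.na(country[[f]])) {
      stop_usage("country record is missing or has invalid field `", f, "`")
    }
  }
  if (country$population <= 0) stop_usage("field `population` must be positive")
  if (country$hepc <= 0) stop_usage("field `hepc` must be positive")
  if (country$oop_share < 0 || country$oop_share > 1) {
    stop_usage("field `oop_share` must lie in [0, 1]")
  }

  q <- quintile_models(country$hepc, country$gini, pegs = pegs)
  labels <- quintile_labels()
  n_sc <- length(spec$multipliers)

  # risk matrix: quintiles x scenarios
  risk <- vapply(spec$multipliers, function(m) {
    oop <- scenario_oop(country$oop_share, m, spec$cost)
    vapply(q$members, che_risk, numeric(1),
           oop_paid = oop, threshold = spec$threshold)
  }, numeric(5))
  risk <- rbind(risk, overall = colMeans(risk))

  cells <- expand.grid(
    quintile = c(labels, "overall"), scenario = spec$labels,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  cells$iso3 <- country$iso3
  cells$multiplier <- rep(spec$multipliers, each = 6L)
  cells$oop_paid <- scenario_oop(country$oop_share, cells$multiplier, spec$cost)
  cells$risk <- as.vector(risk)
  baseline <- risk[, 1L]
  cells$protected <- as.vector(sweep(-risk, 1L, baseline, `+`))
  cells$protected[cells$scenario == "baseline"] <- NA_real_
  pop_share <- c(rep(country$population / 5, 5L), country$population)
  cells$expected_count <- rep(pop_share, n_sc) * cells$risk
  cells[, c("iso3", "quintile", "scenario", "multiplier", "oop_paid",
            "risk", "protected", "expected_count")]
}
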