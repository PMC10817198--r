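#' Fit the catastrophic-expenditure risk model to a country table
#'
#' The central entry point: for every country, builds wealth-quintile gamma
#' income distributions (shape from the Gini index, means pegged to 0.1-0.9
#' times household expenditure per capita), evaluates the CHE risk of the
#' scenario OOP payments, and aggregates the per-country cells to World Bank
#' income groups and WHO regions with standard errors of the mean.
#'
#' With `calibrate = TRUE`, each country's mean income is first re-estimated
#' by [choose_proxy()]: candidate grids around HEpc and GDP per capita are
#' scored against the observed poverty headcount (and FGT-1 gap as the
#' accuracy check), and the winning proxy's calibrated mean replaces HEpc as
#' the quintile base mean.
#'
#' @param countries validated country table (see [read_country_table()] or
#'   [generate_countries()]).
#' @param spec a [scenario_spec()]; cost, threshold and OOP multipliers.
#' @param weighting `"equal"` (default) or `"population"` country weights in
#'   the group summaries.
#' @param calibrate logical; run the calibration stage first.
#' @param grid [calibration_grid()] used when `calibrate = TRUE`.
#' @param pegs quintile mean multipliers.
#' @return an object of class `"che_model"`: list with `countries`, `spec`,
#'   `cells` (per-country x quintile x scenario risk cells),
#'   `summary_income` and `summary_region` (group summaries), `weighting`,
#'   `base_means` (the per-country means actually used) and, when
#'   calibrated, `calibration` (the per-country [choose_proxy()] report).
#' @export
#' @examples
#' syn <- generate_countries(synthetic_config(
#'   n_per_group = c(LIC = 2L, LMIC = 2L, UMIC = 2L, HIC = 2L), seed = 1))
#' fit <- che_model(syn$countries)
#' fit
#' head(summary(fit)$risk_by_income)
che_model <- function(countries, spec = scenario_spec(),
                      weighting = c("equal", "population"),
                      calibrate = FALSE, grid = calibration_grid(),
                      pegs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  if (inherits(countries, "synthetic_countries")) {
    countries <- countries$countries
  }
  weighting <- match.arg(weighting)
  stopifnot(inherits(spec, "scenario_spec"))
  countries <- validate_countries(countries)

  calib <- NULL
  base_means <- countries$hepc
  if (calibrate) {
    calib <- do.call(rbind, lapply(seq_len(nrow(countries)), function(i) {
      choose_proxy(countries[i, ], grid = grid)
    }))
    sel <- calib[calib$selected, ]
    base_means <- sel$chosen_mean[match(countries$iso3, sel$iso3)]
  }

  cells <- do.call(rbind, lapply(seq_len(nrow(countries)), function(i) {
    ci <- countries[i, ]
    ci$hepc <- base_means[i]
    tryCatch(
      country_risk_profile(ci, spec = spec, pegs = pegs),
      error = function(e) stop("country `", countries$iso3[i], "`: ",
                               conditionMessage(e), call. = FALSE)
    )
  }))
  rownames(cells) <- NULL

  structure(
    list(
      countries = countries, spec = spec, cells = cells,
      summary_income = group_summaries(cells, countries, "wb_income",
                                       weighting),
      summary_region = group_summaries(cells, countries, "who_region",
                                       weighting),
      weighting = weighting, base_means = base_means, calibration = calib,
      pegs = pegs
    ),
    class = "che_model"
  )
}

#' Run the full pipeline on a country table
#'
#' Thin wrapper over [che_model()] returning the risk cells and both group
#' summaries as plain data frames.
#'
#' @inheritParams che_model
#' @return list with `cells`, `summary_income`, `summary_region` and the
#'   fitted `model`.
#' @export
run_pipeline <- function(countries, spec = scenario_spec(),
                         weighting = "equal", calibrate = FALSE,
                         grid = calibration_grid()) {
  fit <- che_model(countries, spec = spec, weighting = weighting,
                   calibrate = calibrate, grid = grid)
  list(cells = fit$cells, summary_income = fit$summary_income,
       summary_region = fit$summary_region, model = fit)
}

#' @export
print.che_model <- function(x, digits = 3, ...) {
  cat("Catastrophic health expenditure risk model\n")
  cat(sprintf("  %d countries, cost $%.0f, threshold %.0f%%, %s weighting%s\n",
              nrow(x$countries), x$spec$cost, 100 * x$spec$threshold,
              x$weighting,
              if (!is.null(x$calibration)) ", calibrated means" else ""))
  ov <- x$cells[x$cells$quintile == "overall", ]
  agg <- tapply(ov$risk, ov$scenario, mean)
  agg <- agg[x$spec$labels]
  cat("  mean overall risk by scenario:\n")
  print(round(agg, digits))
  invisible(x)
}

#' Summarize a fitted CHE risk model
#'
#' @param object a `che_model`.
#' @param digits rounding for the presentation tables.
#' @param ... unused.
#' @return a `summary.che_model` list with wide risk and protection tables
#'   by income group and WHO region (rows: group x quintile incl. overall;
#'   columns: scenarios), plus baseline equity gaps per group.
#' @export
summary.che_model <- function(object, digits = 3, ...) {
  wide <- function(summ, value) {
    scen <- intersect(object$spec$labels, unique(summ$scenario))
    if (value == "mean_protected") scen <- setdiff(scen, "baseline")
    qs <- c(quintile_labels(), "overall")
    out <- do.call(rbind, lapply(split(summ, summ$group), function(gg) {
      m <- sapply(scen, function(s) {
        vapply(qs, function(q) {
          v <- gg[[value]][gg$scenario == s & gg$quintile == q]
          if (length(v)) round(v, digits) else NA_real_
        }, numeric(1))
      })
      data.frame(group = gg$group[1], quintile = qs, m,
                 check.names = FALSE, row.names = NULL)
    }))
    rownames(out) <- NULL
    out
  }
  gaps_for <- function(summ) {
    vapply(unique(summ$group), function(g) {
      equity_gap(summ, g, "baseline")
    }, numeric(1))
  }
  structure(
    list(
      risk_by_income = wide(object$summary_income, "mean_risk"),
      risk_by_region = wide(object$summary_region, "mean_risk"),
      protection_by_income = wide(object$summary_income, "mean_protected"),
      protection_by_region = wide(object$summary_region, "mean_protected"),
      equity_gap_income = gaps_for(object$summary_income),
      equity_gap_region = gaps_for(object$summary_region),
      digits = digits, n_countries = nrow(object$countries)
    ),
    class = "summary.che_model"
  )
}

#' @export
print.summary.che_model <- function(x, ...) {
  cat("Proportion of population at risk of CHE, by income group:\n")
  print(x$risk_by_income, row.names = FALSE)
  cat("\nProportion protected by OOP reduction, by income group:\n")
  print(x$protection_by_income, row.names = FALSE)
  cat("\nBaseline poorest-richest equity gap (percentage points):\n")
  print(round(x$equity_gap_income, 1))
  invisible(x)
}

#' @export
coef.che_model <- function(object, ...) {
  shapes <- gini_to_shape(object$countries$gini)
  data.frame(
    iso3 = object$countries$iso3,
    shape = shapes,
    scale = object$base_means / shapes,
    mean = object$base_means,
    gini = object$countries$gini
  )
}

#' Predict CHE risk cells for new countries
#'
#' @param object a fitted `che_model`.
#' @param newdata country table; defaults to the fitted countries.
#' @param ... unused.
#' @return risk-cell data frame as in [country_risk_profile()].
#' @export
predict.che_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$cells)
  if (inherits(newdata, "synthetic_countries")) newdata <- newdata$countries
  newdata <- validate_countries(newdata)
  out <- do.call(rbind, lapply(seq_len(nrow(newdata)), function(i) {
    country_risk_profile(newdata[i, ], spec = object$spec, pegs = object$pegs)
  }))
  rownames(out) <- NULL
  out
}

#' Monte Carlo simulation of CHE indicators from a fitted model
#'
#' Draws incomes from every country's quintile distributions and returns the
#' empirical CHE rates under each scenario — a sampling counterpart of the
#' closed-form risks in `object$cells`, useful as a self-diagnostic.
#'
#' @param object a fitted `che_model`.
#' @param nsim draws per country-quintile (default 10000).
#' @param seed integer seed.
#' @param ... unused.
#' @return data frame with `iso3`, `quintile`, `scenario`, `risk`
#'   (closed form) and `risk_sim` (empirical rate).
#' @export
simulate.che_model <- function(object, nsim = 10000, seed = 1, ...) {
  cells <- object$cells[object$cells$quintile != "overall", ]
  shapes <- gini_to_shape(object$countries$gini)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(object$countries)), function(i) {
      q <- quintile_models(object$base_means[i], object$countries$gini[i],
                           pegs = object$pegs)
      ci <- cells[cells$iso3 == object$countries$iso3[i], ]
      ci$risk_sim <- NA_real_
      for (ql in quintile_labels()) {
        y <- stats::rgamma(nsim, shape = q$shape,
                           scale = q$members[[ql]]$scale)
        rows <- which(ci$quintile == ql)
        for (r in rows) {
          ci$risk_sim[r] <- mean(ci$oop_paid[r] >= object$spec$threshold * y)
        }
      }
      ci
    }))
    rownames(out) <- NULL
    out[, c("iso3", "quintile", "scenario", "risk", "risk_sim")]
  })
}

#' Residuals of the calibration stage
#'
#' @param object a `che_model` fitted with `calibrate = TRUE`.
#' @param ... unused.
#' @return named vector of combined poverty-statistic residuals (selected
#'   proxy) per country.
#' @export
residuals.che_model <- function(object, ...) {
  if (is.null(object$calibration)) {
    stop_usage("model was fitted without calibration; no residuals")
  }
  sel <- object$calibration[object$calibration$selected, ]
  stats::setNames(sel$residual, sel$iso3)
}

#' Bar plot of group mean risks with SEM whiskers
#'
#' @param x a fitted `che_model`.
#' @param grouping `"wb_income"` or `"who_region"`.
#' @param scenario scenario label to plot (default `"baseline"`).
#' @param ... passed to [graphics::barplot()].
#' @return the bar midpoints, invisibly.
#' @export
plot.che_model <- function(x, grouping = c("wb_income", "who_region"),
                           scenario = "baseline", ...) {
  grouping <- match.arg(grouping)
  summ <- if (grouping == "wb_income") x$summary_income else x$summary_region
  summ <- summ[summ$scenario == scenario & summ$quintile != "overall", ]
  groups <- unique(summ$group)
  qs <- quintile_labels()
  m <- sapply(groups, function(g) {
    vapply(qs, function(q) summ$mean_risk[summ$group == g &
                                            summ$quintile == q], numeric(1))
  })
  s <- sapply(groups, function(g) {
    vapply(qs, function(q) summ$sem_risk[summ$group == g &
                                           summ$quintile == q], numeric(1))
  })
  mids <- graphics::barplot(m, beside = TRUE, legend.text = qs,
                            ylim = c(0, max(m + s) * 1.15),
                            ylab = "CHE risk (proportion)",
                            main = paste("CHE risk,", scenario), ...)
  nz <- s > 0
  if (any(nz)) {
    graphics::arrows(mids[nz], (m - s)[nz], mids[nz], (m + s)[nz],
                     angle = 90, code = 3, length = 0.02)
  }
  invisible(mids)
}
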