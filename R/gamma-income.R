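#' Gini index of a gamma income distribution
#'
#' For incomes following a gamma law with shape \eqn{\alpha}, the Gini index
#' depends on the shape alone:
#' \deqn{G(\alpha) = \frac{\Gamma(\alpha + 1/2)}{\Gamma(\alpha + 1)\sqrt{\pi}}.}
#' The scale parameter rescales incomes uniformly and so leaves relative
#' inequality unchanged. Evaluated in log-space for numerical stability at
#' large shapes.
#'
#' @param shape positive gamma shape parameter; vectorized.
#' @return Gini index in (0, 1); strictly decreasing in `shape`, with
#'   `shape_to_gini(1) == 0.5` (the exponential distribution).
#' @seealso [gini_to_shape()] for the inverse mapping.
#' @export
#' @examples
#' shape_to_gini(1)    # 0.5
#' shape_to_gini(c(0.5, 2))
shape_to_gini <- function(shape) {
  if (!is.numeric(shape) || length(shape) < 1L || any(!is.finite(shape)) ||
      any(shape <= 0)) {
    stop_domain("`shape` must be positive and finite")
  }
  exp(lgamma(shape + 0.5) - lgamma(shape + 1) - 0.5 * log(pi))
}

#' Gamma shape parameter matching a Gini index
#'
#' Inverts [shape_to_gini()] by bisection on the bracket
#' \eqn{\alpha \in [10^{-3}, 10^{3}]}, to an absolute tolerance of 1e-10 on
#' the Gini scale. The mapping is strictly monotone so the root is unique.
#'
#' @param gini Gini index; must lie in \[0.01, 0.99\] (values outside error
#'   rather than clamp, so bad data are surfaced instead of hidden).
#' @return the shape parameter alpha such that
#'   `abs(shape_to_gini(alpha) - gini) <= 1e-10`.
#' @export
#' @examples
#' gini_to_shape(0.5)  # 1: the exponential case
gini_to_shape <- function(gini) {
  if (!is.numeric(gini) || length(gini) < 1L || any(!is.finite(gini))) {
    stop_domain("`gini` must be numeric and finite")
  }
  if (any(gini < 0.01 | gini > 0.99)) {
    stop_domain("`gini` must lie in [0.01, 0.99]; got ",
                paste(signif(gini[gini < 0.01 | gini > 0.99], 4), collapse = ", "))
  }
  vapply(gini, function(g) {
    lo <- 1e-3
    hi <- 1e3
    # shape_to_gini is decreasing: g(lo) > target > g(hi) on this bracket.
    # 80 halvings collapse the bracket to ~4e-22 relative, well inside the
    # 1e-10 Gini tolerance.
    for (i in seq_len(80L)) {
      mid <- 0.5 * (lo + hi)
      if (shape_to_gini(mid) > g) lo <- mid else hi <- mid
    }
    0.5 * (lo + hi)
  }, numeric(1))
}

#' Gamma income distribution for a country
#'
#' Builds the income model used throughout the package: a gamma distribution
#' whose shape is determined by the country's Gini index (via
#' [gini_to_shape()]) and whose scale is set so the distribution mean equals
#' the income proxy (household expenditure per capita, annual USD).
#'
#' @param mean_income mean income in USD per person-year; positive.
#' @param gini Gini index in \[0.01, 0.99\].
#' @return an object of class `"gamma_income"`: a list with elements `shape`,
#'   `scale`, `mean` (= shape * scale) and `gini`.
#' @export
#' @examples
#' m <- income_model(1000, 0.5)
#' m$shape  # 1
#' poverty_headcount(m, 1000)  # 1 - exp(-1)
income_model <- function(mean_income, gini) {
  check_positive_scalar(mean_income, "mean_income")
  shape <- gini_to_shape(gini)
  new_gamma_income(shape = shape, scale = mean_income / shape)
}

new_gamma_income <- function(shape, scale) {
  check_positive_scalar(shape, "shape")
  check_positive_scalar(scale, "scale")
  structure(
    list(shape = shape, scale = scale, mean = shape * scale,
         gini = shape_to_gini(shape)),
    class = "gamma_income"
  )
}

#' @export
print.gamma_income <- function(x, ...) {
  cat(sprintf(
    "Gamma income distribution: mean %.2f USD/yr (shape %.4f, scale %.2f, Gini %.3f)\n",
    x$mean, x$shape, x$scale, x$gini))
  invisible(x)
}

#' Wealth-quintile income distributions
#'
#' Constructs five gamma income distributions sharing the shape implied by the
#' national Gini index, with means pegged to multiples of the national mean
#' income (0.1, 0.3, 0.5, 0.7 and 0.9 by default), ordered poorest to richest.
#' Because the shape is shared, every member reproduces the national Gini;
#' only the scale differs.
#'
#' @param base_mean national mean income (household expenditure per capita,
#'   USD per person-year).
#' @param gini national Gini index.
#' @param pegs multipliers applied to `base_mean` to obtain quintile means;
#'   must be positive and strictly increasing.
#' @return an object of class `"quintile_set"`: a list with `members` (five
#'   `gamma_income` objects named poorest/poor/middle/rich/richest),
#'   `base_mean`, `peg_factors` and the shared `shape`.
#' @export
#' @examples
#' q <- quintile_models(1000, 0.5)
#' sapply(q$members, `[[`, "mean")  # 100 300 500 700 900
quintile_models <- function(base_mean, gini, pegs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  check_positive_scalar(base_mean, "base_mean")
  if (length(pegs) != 5L || any(pegs <= 0) || any(diff(pegs) <= 0)) {
    stop_domain("`pegs` must be five positive strictly increasing multipliers")
  }
  shape <- gini_to_shape(gini)
  members <- lapply(pegs * base_mean, function(m) {
    new_gamma_income(shape = shape, scale = m / shape)
  })
  names(members) <- quintile_labels()
  structure(
    list(members = members, base_mean = base_mean, peg_factors = pegs,
         shape = shape),
    class = "quintile_set"
  )
}

quintile_labels <- function() c("poorest", "poor", "middle", "rich", "richest")

#' @export
print.quintile_set <- function(x, ...) {
  cat(sprintf("Quintile set: base mean %.2f USD/yr, shared shape %.4f\n",
              x$base_mean, x$shape))
  cat("  means:", paste(sprintf("%.1f", vapply(x$members, `[[`, 0, "mean")),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Poverty headcount under a gamma income law
#'
#' The fraction of the population with income below `line`: the regularized
#' lower incomplete gamma function, i.e. the model CDF at the poverty line.
#'
#' @param model a `gamma_income` object.
#' @param line poverty line, USD per person-year; non-negative. Vectorized.
#' @return headcount ratio in \[0, 1\].
#' @export
poverty_headcount <- function(model, line) {
  stopifnot(inherits(model, "gamma_income"))
  if (!is.numeric(line) || any(!is.finite(line)) || any(line < 0)) {
    stop_domain("`line` must be non-negative and finite")
  }
  stats::pgamma(line, shape = model$shape, scale = model$scale)
}

#' FGT-1 poverty gap under a gamma income law
#'
#' The mean relative shortfall below the poverty line over the whole
#' population, \eqn{E[\max(0, (L - y)/L)]}. For a gamma law this has the
#' closed form
#' \deqn{F(L;\alpha,\beta) - \frac{\mu}{L} F(L;\alpha+1,\beta),}
#' using the identity \eqn{E[y \cdot 1\{y<L\}] = \mu F(L;\alpha+1,\beta)}.
#'
#' @param model a `gamma_income` object.
#' @param line poverty line, USD per person-year; strictly positive.
#'   Vectorized.
#' @return poverty-gap index in \[0, 1\]; never exceeds the headcount at the
#'   same line.
#' @export
poverty_gap <- function(model, line) {
  stopifnot(inherits(model, "gamma_income"))
  if (!is.numeric(line) || any(!is.finite(line)) || any(line <= 0)) {
    stop_domain("`line` must be positive and finite")
  }
  stats::pgamma(line, shape = model$shape, scale = model$scale) -
    (model$mean / line) *
      stats::pgamma(line, shape = model$shape + 1, scale = model$scale)
}

#' Draw incomes from a gamma income model
#'
#' Utility used by the Monte Carlo cross-checks and by the replicate-based
#' calibration diagnostics; deterministic when a seed is supplied, and leaves
#' the caller's RNG state untouched.
#'
#' @param model a `gamma_income` object.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return numeric vector of `n` positive incomes (USD per person-year).
#' @export
sample_incomes <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "gamma_income"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop_domain("`n` must be a positive count")
  }
  draw <- function() stats::rgamma(n, shape = model$shape, scale = model$scale)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
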