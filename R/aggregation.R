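#' Group-level risk and protection summaries
#'
#' Aggregates per-country risk cells (from [country_risk_profile()]) to World
#' Bank income groups or WHO regions. Each (group, quintile, scenario) cell
#' reports the mean risk and mean protected fraction across the group's
#' countries together with the standard error of the mean. Countries are the
#' unit of observation: the default weighting is equal; population weighting
#' is available as an option.
#'
#' SEM uses the n-1 sample standard deviation divided by sqrt(n); groups with
#' a single country report `sem = 0` with a logged note, keeping the output
#' rectangular. Under population weighting the mean is the normalized
#' weighted mean and the SEM uses the weighted n-1 variance, which reduces
#' exactly to the equal-weight formulas when populations are equal.
#'
#' @param cells data frame of risk cells with columns `iso3`, `quintile`,
#'   `scenario`, `risk`, `protected`.
#' @param countries country table carrying `iso3`, `income_group`,
#'   `who_region`, `population`.
#' @param grouping `"wb_income"` or `"who_region"`.
#' @param weighting `"equal"` (default) or `"population"`.
#' @return data frame with columns `grouping`, `group`, `quintile`,
#'   `scenario`, `mean_risk`, `sem_risk`, `mean_protected`, `sem_protected`,
#'   `n_countries`.
#' @export
group_summaries <- function(cells, countries,
                            grouping = c("wb_income", "who_region"),
                            weighting = c("equal", "population")) {
  grouping <- match.arg(grouping)
  weighting <- match.arg(weighting)
  key <- if (grouping == "wb_income") "income_group" else "who_region"

  unknown <- setdiff(unique(cells$iso3), countries$iso3)
  if (length(unknown)) {
    stop_usage("risk cells reference countries absent from the table: ",
               paste(unknown, collapse = ", "))
  }
  idx <- match(cells$iso3, countries$iso3)
  grp <- as.character(countries[[key]])[idx]
  if (anyNA(grp)) {
    stop_usage("missing `", key, "` label for countries: ",
               paste(unique(cells$iso3[is.na(grp)]), collapse = ", "))
  }
  w <- if (weighting == "population") countries$population[idx] else
    rep(1, nrow(cells))

  split_key <- interaction(grp, cells$quintile, cells$scenario, drop = TRUE,
                           lex.order = TRUE)
  pieces <- split(seq_len(nrow(cells)), split_key)

  wstats <- function(x, wt) {
    keep <- !is.na(x)
    x <- x[keep]; wt <- wt[keep]
    n <- length(x)
    if (n == 0L) return(c(NA_real_, NA_real_, 0))
    wt <- wt / sum(wt)
    m <- sum(wt * x)
    if (n == 1L) return(c(m, 0, 1))
    v <- sum(wt * (x - m)^2) * n / (n - 1)
    c(m, sqrt(v / n), n)
  }

  rows <- lapply(pieces, function(ii) {
    r <- wstats(cells$risk[ii], w[ii])
    p <- wstats(cells$protected[ii], w[ii])
    data.frame(
      grouping = grouping,
      group = grp[ii[1L]],
      quintile = as.character(cells$quintile[ii[1L]]),
      scenario = as.character(cells$scenario[ii[1L]]),
      mean_risk = r[1L], sem_risk = r[2L],
      mean_protected = p[1L], sem_protected = p[2L],
      n_countries = as.integer(r[3L])
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$n_countries == 1L)) {
    message("groups with a single country report SEM = 0: ",
            paste(unique(out$group[out$n_countries == 1L]), collapse = ", "))
  }
  out[order(out$group, match(out$quintile, c(quintile_labels(), "overall")),
            out$scenario), , drop = FALSE]
}

#' Equity gap between the poorest and richest quintiles
#'
#' @param summaries output of [group_summaries()].
#' @param group group label (e.g. `"LIC"` or `"AFR"`).
#' @param scenario scenario label (e.g. `"baseline"`).
#' @return the gap in percentage points:
#'   `100 * (poorest mean risk - richest mean risk)`.
#' @export
equity_gap <- function(summaries, group, scenario) {
  pick <- function(q) {
    i <- summaries$group == group & summaries$scenario == scenario &
      summaries$quintile == q
    if (sum(i) != 1L) {
      stop_usage("no unique `", q, "` cell for group `", group,
                 "`, scenario `", scenario, "`")
    }
    summaries$mean_risk[i]
  }
  100 * (pick("poorest") - pick("richest"))
}
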