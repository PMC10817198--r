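country_columns <- function() {
  list(
    mandatory = c("iso3", "name", "income_group", "who_region", "population",
                  "gini", "hepc", "oop_share", "pov_headcount_190",
                  "pov_headcount_320"),
    optional = c("gdp_pc", "pov_gap_215", "pct_urban", "data_year")
  )
}

#' Read and validate a country indicator table
#'
#' Reads a comma-separated country table (UTF-8, header row; column names
#' matched case-insensitively). Mandatory columns: `iso3`, `name`,
#' `income_group` (LIC/LMIC/UMIC/HIC), `who_region`
#' (AFR/AMR/EMR/EUR/SEAR/WPR), `population`, `gini`, `hepc`, `oop_share`,
#' `pov_headcount_190`, `pov_headcount_320`. Optional: `gdp_pc`,
#' `pov_gap_215`, `pct_urban`, `data_year`. Fraction-valued columns supplied
#' on the percent scale (e.g. a Gini of 35) are auto-detected and divided by
#' 100 with a warning. Rows violating the field invariants are dropped with
#' per-row diagnostics naming the offending field.
#'
#' @param path path to the CSV file.
#' @return a validated country data frame.
#' @export
read_country_table <- function(path) {
  if (!file.exists(path)) stop_usage("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  names(df) <- tolower(names(df))
  cols <- country_columns()
  missing <- setdiff(cols$mandatory, names(df))
  if (length(missing)) {
    stop_usage("missing mandatory columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) stop_usage("country table is empty")
  for (opt in cols$optional) if (is.null(df[[opt]])) df[[opt]] <- NA
  validate_countries(df)
}

#' Validate country records
#'
#' Applies the field invariants (Gini in (0,1), positive HEpc and population,
#' shares and poverty statistics in \[0,1\], known group labels), converting
#' percent-scale fraction columns with a warning, and dropping invalid rows
#' with diagnostics that name the row and field.
#'
#' @param df a country data frame (see [read_country_table()]).
#' @return the validated (possibly reduced) data frame.
#' @export
validate_countries <- function(df) {
  frac_cols <- c("gini", "oop_share", "pov_headcount_190",
                 "pov_headcount_320", "pov_gap_215", "pct_urban")
  for (cc in intersect(frac_cols, names(df))) {
    x <- df[[cc]]
    # column-level detection: a fraction column reported on the percent
    # scale (e.g. Gini 35) has its bulk above 1; a lone out-of-range value
    # in an otherwise fractional column is a bad row, not a unit problem
    if (any(!is.na(x)) && stats::median(x, na.rm = TRUE) > 1.5 &&
        max(x, na.rm = TRUE) <= 100) {
      warning("column `", cc, "` looks percent-scaled; dividing by 100",
              call. = FALSE)
      df[[cc]] <- x / 100
    }
  }

  problems <- character(0)
  bad_row <- rep(FALSE, nrow(df))
  flag <- function(rows, field, why) {
    if (any(rows)) {
      problems <<- c(problems, sprintf("row %d: `%s` %s",
                                       which(rows), field, why))
      bad_row <<- bad_row | rows
    }
  }
  isna <- function(x) is.na(x)
  flag(isna(df$gini) | df$gini <= 0 | df$gini >= 1, "gini",
       "must lie in (0, 1)")
  flag(isna(df$hepc) | df$hepc <= 0, "hepc", "must be positive")
  flag(isna(df$population) | df$population <= 0, "population",
       "must be positive")
  flag(isna(df$oop_share) | df$oop_share < 0 | df$oop_share > 1, "oop_share",
       "must lie in [0, 1]")
  for (cc in c("pov_headcount_190", "pov_headcount_320")) {
    flag(isna(df[[cc]]) | df[[cc]] < 0 | df[[cc]] > 1, cc,
         "must lie in [0, 1]")
  }
  if ("pov_gap_215" %in% names(df)) {
    flag(!isna(df$pov_gap_215) & (df$pov_gap_215 < 0 | df$pov_gap_215 > 1),
         "pov_gap_215", "must lie in [0, 1]")
  }
  flag(isna(df$income_group) |
         !df$income_group %in% c("LIC", "LMIC", "UMIC", "HIC"),
       "income_group", "must be one of LIC/LMIC/UMIC/HIC")
  flag(isna(df$who_region) |
         !df$who_region %in% c("AFR", "AMR", "EMR", "EUR", "SEAR", "WPR"),
       "who_region", "must be one of AFR/AMR/EMR/EUR/SEAR/WPR")

  if (length(problems)) {
    warning("dropping ", sum(bad_row), " invalid row(s):\n  ",
            paste(problems, collapse = "\n  "), call. = FALSE)
    df <- df[!bad_row, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop_usage("no valid country records remain")
  rownames(df) <- NULL
  df
}

#' Write a country table
#'
#' Inverse of [read_country_table()]: writes the table as CSV so that
#' reading it back reproduces the records.
#'
#' @param countries country data frame (or a `synthetic_countries` object,
#'   whose `$countries` element is written).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_country_table <- function(countries, path) {
  if (inherits(countries, "synthetic_countries")) {
    countries <- countries$countries
  }
  utils::write.csv(countries, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write pipeline results as delimited tables
#'
#' Writes the per-country risk cells unrounded (`cells.csv`), group risk
#' tables in the wide quintile-by-scenario layout
#' (`risk_by_income.csv`, `risk_by_region.csv`), the corresponding protection
#' tables (`protection_by_income.csv`, `protection_by_region.csv`, rounded to
#' `digits`), and a `run_metadata.json` echo of the configuration. Rounding
#' is applied only in the presentation tables, so protection tables are
#' differences of unrounded risks.
#'
#' @param model a fitted [che_model()] object.
#' @param out_dir output directory (created if missing).
#' @param digits decimal places for the presentation tables (default 3).
#' @return character vector of written file paths, invisibly.
#' @export
write_results <- function(model, out_dir, digits = 3) {
  stopifnot(inherits(model, "che_model"))
  if (digits < 0) stop_usage("`digits` must be >= 0")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir)

  paths <- file.path(out_dir, c(
    "cells.csv", "risk_by_income.csv", "risk_by_region.csv",
    "protection_by_income.csv", "protection_by_region.csv",
    "run_metadata.json"))
  utils::write.csv(model$cells, paths[1], row.names = FALSE)

  wide <- function(summ, value) {
    scen <- intersect(model$spec$labels, unique(summ$scenario))
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
  utils::write.csv(wide(model$summary_income, "mean_risk"), paths[2],
                   row.names = FALSE)
  utils::write.csv(wide(model$summary_region, "mean_risk"), paths[3],
                   row.names = FALSE)
  utils::write.csv(wide(model$summary_income, "mean_protected"), paths[4],
                   row.names = FALSE)
  utils::write.csv(wide(model$summary_region, "mean_protected"), paths[5],
                   row.names = FALSE)

  meta <- list(
    package = "cherisk",
    version = as.character(utils::packageVersion("cherisk")),
    cost = model$spec$cost, threshold = model$spec$threshold,
    multipliers = model$spec$multipliers, weighting = model$weighting,
    calibrated = !is.null(model$calibration),
    n_countries = nrow(model$countries),
    digits = digits,
    n_warnings = length(model$warnings %||% character(0)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(meta, paths[6], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
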