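`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random number generator seeded at `seed`,
#' restoring the caller's RNG state afterwards so package functions never
#' perturb user-level reproducibility.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_domain <- function(...) {
  stop(structure(
    class = c("cherisk_domain_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_usage <- function(...) {
  stop(structure(
    class = c("cherisk_usage_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_domain("`", name, "` must be a single positive finite number")
  }
  invisible(x)
}
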