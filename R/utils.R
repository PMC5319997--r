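# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that seeded stages do not
#' perturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

geometric_mean <- function(x) exp(mean(log(x)))

# Derive per-stage seeds from one master seed by fixed offsets, kept within
# 32-bit integer range.
stage_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 7919 + offset) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  }
  x
}
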