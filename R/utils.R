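#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so generators are pure functions of their arguments.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a stage seed from a master seed, kept inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset * 12347) %% 2147483587)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_range <- function(x, name, lo, hi, open_lo = FALSE, open_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("`%s` must be a single finite number", name)
  bad <- (open_lo && x <= lo) || (!open_lo && x < lo) ||
    (open_hi && x >= hi) || (!open_hi && x > hi)
  if (bad) stopf("`%s` = %g is outside its allowed range [%g, %g]", name, x, lo, hi)
  invisible(x)
}
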