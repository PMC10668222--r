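## internal argument checks

stop_if_not_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%g, %g], got %g", name, lower, upper, x),
         call. = FALSE)
  invisible(x)
}

stop_if_not_numeric <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)))
    stop(sprintf("'%s' must be a non-empty finite numeric vector", name),
         call. = FALSE)
  if (any(x < lower) || any(x > upper))
    stop(sprintf("'%s' must lie within [%g, %g]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

stop_if_not_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x %% 1 != 0)
    stop(sprintf("'%s' must be a positive integer", name), call. = FALSE)
  invisible(as.integer(x))
}

## run an expression under a local, seeded RNG state; the caller's RNG
## stream is left untouched
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stop_if_not_number(seed, "seed")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
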