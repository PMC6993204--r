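# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

row_norms <- function(m) {
  if (is.null(dim(m))) return(abs(m))
  sqrt(rowSums(m^2))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(sprintf("`%s` must be finite numeric", name), call. = FALSE)
  invisible(x)
}

as_vec3 <- function(x, name) {
  check_finite(x, name)
  if (length(x) != 3) stop(sprintf("`%s` must be a 3-vector", name), call. = FALSE)
  as.numeric(x)
}

# Trapezoid-free cumulative sum integral as used throughout the metric
# definitions: sum over n of value(n) * (t(n) - t(n-1)).
sum_dt <- function(values, t) {
  n <- length(t)
  if (n < 2) return(0)
  sum(values[-1] * diff(t))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
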