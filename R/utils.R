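# Internal helpers shared across modules.

# Derive a reproducible sub-seed from a base seed and a stream label.
# Keeps everything below .Machine$integer.max (R seeds are 32-bit).
sub_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483629L)
}

# Evaluate expr with a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Linear interpolation with flat extrapolation at both ends.
interp1_flat <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, method = "linear", rule = 2)$y
}

stop_gf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop_gf(fmt, ...)
  invisible(TRUE)
}
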