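# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global `.Random.seed` so that seeded generator
#' calls do not perturb user RNG state.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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

# Derive a deterministic 31-bit sub-seed from a base seed and an index.
# Linear congruential mix; avoids correlated streams when trials share a seed.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  i <- as.double(index) + 1
  as.integer((s * 48271 + i * 16807 + s * i) %% 2147483647)
}

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_in <- function(x, name, lower, upper,
                             lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param("`%s` must be a finite numeric scalar", name)
  lo_ok <- if (lower_open) x > lower else x >= lower
  hi_ok <- if (upper_open) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_param("`%s` = %g outside %s%g, %g%s", name, x,
               if (lower_open) "(" else "[", lower, upper,
               if (upper_open) ")" else "]")
  invisible(x)
}

# Hanning (raised-cosine) taper of length n, matching the periodic-symmetric
# convention used for spectral windows: w[k] = 0.5 (1 - cos(2 pi (k-1)/(n-1))).
hanning <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

# FFT-based linear convolution of x with kernel h, truncated to length(x)
# (causal: output[k] = sum_j h[j] x[k - j + 1]).
conv_causal <- function(x, h) {
  n <- length(x)
  m <- length(h)
  nfft <- stats::nextn(n + m - 1L, 2L)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                       stats::fft(c(h, numeric(nfft - m))), inverse = TRUE)) / nfft
  y[seq_len(n)]
}
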