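# Detrended fluctuation analysis: integrated profile, log2-equidistant box
# grid, forward/backward-averaged RMS fluctuations, exponent fitting, and
# assembly of per-window Hurst time courses.

#' Integrated (cumulatively summed, mean-centred) profile
#'
#' \eqn{y(k) = \sum_{i \le k} (x(i) - \bar x)}. The last element is zero up
#' to rounding because deviations from the mean sum to zero.
#'
#' @param x Numeric series, length >= 2, finite.
#' @return List of class `integrated_profile`: `y`, `N`, `x_mean`.
#' @export
integrate_profile <- function(x) {
  if (length(x) < 2L) stop_param("series too short")
  if (!all(is.finite(x))) stop_param("non-finite values in input")
  xm <- mean(x)
  structure(list(y = cumsum(x - xm), N = length(x), x_mean = xm),
            class = "integrated_profile")
}

#' Box-size grid, log2-equidistant in \[n_min, N/4\]
#'
#' `k_sizes` box sizes equidistant on a log2 scale between `n_min` and
#' `floor(N/4)`, rounded to the nearest integer and de-duplicated
#' preserving order. If rounding collapses sizes, the realized (smaller)
#' count is returned rather than padded.
#'
#' @param N Series length; must satisfy `floor(N/4) > n_min` (N >= 44 for
#'   the default `n_min = 10`).
#' @param n_min Smallest box size (default 10).
#' @param k_sizes Nominal number of sizes (default 25).
#' @return Object of class `box_grid`: integer vector `sizes` plus bounds.
#' @export
make_box_grid <- function(N, n_min = 10, k_sizes = 25) {
  n_max <- floor(N / 4)
  if (n_max <= n_min)
    stop_param("window too short for DFA (N = %d gives N/4 = %d <= n_min = %d)",
               N, n_max, n_min)
  sizes <- unique(as.integer(round(
    2^seq(log2(n_min), log2(n_max), length.out = k_sizes))))
  structure(list(sizes = sizes, n_min = as.integer(n_min),
                 n_max = as.integer(n_max), k_sizes = as.integer(k_sizes)),
            class = "box_grid")
}

# RMS of residuals after per-box least-squares linear detrending, for one
# partition direction. Y is the n x nb matrix of box contents.
box_detrended_rms <- function(ybox, n) {
  nb <- length(ybox) / n
  Y <- matrix(ybox, nrow = n)
  t <- as.numeric(seq_len(n))   # double: sums of t^2 overflow integers
  St <- sum(t); Stt <- sum(t * t)
  det <- n * Stt - St * St
  Sy <- colSums(Y)
  Sty <- as.numeric(crossprod(t, Y))
  slope <- (n * Sty - St * Sy) / det
  icpt <- (Sy - slope * St) / n
  resid <- Y - outer(t, slope) - matrix(icpt, nrow = n, ncol = nb,
                                        byrow = TRUE)
  sqrt(mean(resid^2))
}

#' RMS fluctuation function over a box grid
#'
#' For each box size n the profile is partitioned into `floor(N/n)`
#' non-overlapping boxes both from the start (forward) and from the end
#' (backward); within each box the least-squares line is removed and the
#' RMS of the residuals over the covered samples is taken. `F(n)` is the
#' mean of the forward and backward RMS values, so trailing samples that
#' do not fill a complete box still contribute through the opposite
#' direction.
#'
#' @param profile An [integrate_profile] result (or a raw series, which is
#'   integrated first).
#' @param grid A [make_box_grid] result; `NULL` builds the default grid.
#' @return Object of class `fluctuation_function`: `n`, `F`.
#' @export
fluctuation <- function(profile, grid = NULL) {
  if (!inherits(profile, "integrated_profile"))
    profile <- integrate_profile(profile)
  if (is.null(grid)) grid <- make_box_grid(profile$N)
  y <- profile$y
  N <- profile$N
  if (max(grid$sizes) > N) stop_param("grid exceeds profile length")
  Fv <- vapply(grid$sizes, function(n) {
    nb <- N %/% n
    fwd <- box_detrended_rms(y[seq_len(nb * n)], n)
    bwd <- box_detrended_rms(y[(N - nb * n + 1L):N], n)
    (fwd + bwd) / 2
  }, numeric(1))
  structure(list(n = grid$sizes, F = Fv), class = "fluctuation_function")
}

#' DFA scaling exponent (Hurst exponent) of a series
#'
#' Ordinary least-squares fit of `log2 F(n)` against `log2 n` over the box
#' grid; the slope is the DFA scaling exponent H (H_BB for broadband input,
#' H_alpha for an alpha amplitude envelope).
#'
#' @param x Numeric series, or a precomputed `fluctuation_function`.
#' @param grid Box grid, or `NULL` for the default `[10, N/4]`, 25 sizes.
#' @return Object of class `dfa_result`: `H`, `intercept`, `r_squared`,
#'   `fluctuations`.
#' @export
dfa_exponent <- function(x, grid = NULL) {
  fl <- if (inherits(x, "fluctuation_function")) x else fluctuation(x, grid)
  if (any(fl$F <= 0))
    stop_param("degenerate signal: zero fluctuation at some box size %s",
               "(constant or exactly linear input)")
  u <- log2(fl$n); v <- log2(fl$F)
  fit <- stats::lm.fit(cbind(1, u), v)
  H <- unname(fit$coefficients[2])
  r2 <- 1 - sum(fit$residuals^2) / sum((v - mean(v))^2)
  structure(list(H = H, intercept = unname(fit$coefficients[1]),
                 r_squared = r2, fluctuations = fl),
            class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("DFA: H = %.3f (R^2 = %.3f) over %d box sizes in [%d, %d]\n",
              x$H, x$r_squared, length(x$fluctuations$n),
              min(x$fluctuations$n), max(x$fluctuations$n)))
  invisible(x)
}

#' Per-window Hurst-exponent time course
#'
#' Runs [dfa_exponent] on every window of a [window_series] (windows come
#' Hanning-tapered from [sliding_windows] by default, matching the use of
#' the taper to avoid edge effects on short windows) and exponentially
#' smooths consecutive windows within each trial. For 2 s windows at
#' 128 Hz the default grid is \[10, 64\] samples, i.e. 78 ms to 0.5 s —
#' within the admissible timescale range
#' \eqn{[\max(k+2, F_s/F_{max}), \min(N/4, F_s/F_{min})]} with k = 1
#' (linear detrending) for a 0.5–45 Hz band at 128 Hz.
#'
#' Degenerate windows yield `NA` with a warning, not an error.
#'
#' @param ws A [window_series].
#' @param alpha_smooth Exponential smoothing constant (1 = no smoothing).
#' @param n_min,k_sizes Box-grid parameters.
#' @return Object of class `feature_timecourse`: `values`
#'   (trials x channels x windows), `window_end_times`, `condition`,
#'   `channels`, `r_squared` (same shape as `values`, unsmoothed).
#' @export
h_timecourse <- function(ws, alpha_smooth = 0.3, n_min = 10, k_sizes = 25) {
  stopifnot(inherits(ws, "window_series"))
  d <- dim(ws$windows)
  grid <- make_box_grid(d[4], n_min, k_sizes)
  values <- array(NA_real_, d[1:3])
  r2 <- array(NA_real_, d[1:3])
  n_bad <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    h <- numeric(d[3])
    for (k in seq_len(d[3])) {
      res <- tryCatch(dfa_exponent(ws$windows[i, j, k, ], grid),
                      error = function(e) NULL)
      if (is.null(res)) { h[k] <- NA_real_; n_bad <- n_bad + 1L }
      else { h[k] <- res$H; r2[i, j, k] <- res$r_squared }
    }
    values[i, j, ] <- exp_smooth(h, alpha_smooth)
  }
  if (n_bad > 0)
    warning(sprintf("%d degenerate window(s) yielded NA", n_bad))
  feature_timecourse(values, ws$window_end_times, ws$condition, ws$channels,
                     r_squared = r2)
}

#' Per-window feature time course container
#'
#' @param values Array, trials x channels x windows.
#' @param window_end_times Window end times (s).
#' @param condition Per-trial condition labels.
#' @param channels Channel labels.
#' @param r_squared Optional array of per-window linear-fit R^2.
#' @return Object of class `feature_timecourse`.
#' @export
feature_timecourse <- function(values, window_end_times, condition, channels,
                               r_squared = NULL) {
  stopifnot(length(dim(values)) == 3L,
            dim(values)[3] == length(window_end_times))
  structure(list(values = values, window_end_times = window_end_times,
                 condition = condition, channels = channels,
                 r_squared = r_squared),
            class = "feature_timecourse")
}

#' @export
print.feature_timecourse <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("feature_timecourse: %d trials x %d channels x %d windows\n",
              d[1], d[2], d[3]))
  invisible(x)
}

# Power-of-two bracketing of timescale bounds in seconds -> box sizes in
# samples: lower = 2^round(log2(fs * tmin)), upper = 2^floor(log2(fs * tmax)).
# Reproduces the conventional published brackets ([2^8, 2^11] for 2-20 s at
# 128 Hz; [2^8, 2^10] for 2-8 s).
stitched_box_bounds <- function(fs, timescale_bounds) {
  lo <- 2^round(log2(fs * timescale_bounds[1]))
  hi <- 2^floor(log2(fs * timescale_bounds[2]))
  c(lo, hi)
}

#' DFA on a stitched segment over long timescales
#'
#' Same DFA machinery applied to a cross-trial [stitch]ed segment with a
#' log2-equidistant grid inside the requested timescale bounds. Used for
#' the alpha-envelope exponent H_alpha (2–20 s timescales on 80 s
#' segments) and for broadband verification on the same segments.
#'
#' @param seg A [stitched_segment].
#' @param timescale_bounds Two seconds values, e.g. `c(2, 20)`; converted
#'   to power-of-two box-size bounds in samples.
#' @param k_sizes Number of box sizes.
#' @return A `dfa_result`.
#' @export
stitched_dfa <- function(seg, timescale_bounds = c(2, 20), k_sizes = 25) {
  stopifnot(inherits(seg, "stitched_segment"))
  b <- stitched_box_bounds(seg$fs, timescale_bounds)
  N <- length(seg$series)
  if (b[2] > N / 4)
    stop_param("largest box %d exceeds segment length / 4 (%g)", b[2], N / 4)
  sizes <- unique(as.integer(round(
    2^seq(log2(b[1]), log2(b[2]), length.out = k_sizes))))
  grid <- structure(list(sizes = sizes, n_min = b[1], n_max = b[2],
                         k_sizes = as.integer(k_sizes)), class = "box_grid")
  dfa_exponent(seg$series, grid)
}
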