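# Preprocessing: band-pass filtering, downsampling, sliding-window
# extraction, alpha amplitude envelope, cross-trial stitching, exponential
# smoothing.

#' Zero-phase Butterworth band-pass filter
#'
#' Fourth-order (by default) Butterworth applied forward and backward
#' (zero net phase; effective magnitude order doubled by the two passes)
#' with 1 s reflect padding at each trial edge to suppress startup
#' transients on short trials.
#'
#' @param x Numeric series, or a [trial_set] (filtered per trial/channel).
#' @param low,high Band edges in Hz, `0 < low < high < fs/2`.
#' @param fs Sampling rate (Hz); taken from the `trial_set` if given one.
#' @param order Designed filter order (default 4).
#' @param pad_s Reflect padding at each edge, in seconds.
#' @return Object of the same type as `x`, filtered.
#' @export
bandpass <- function(x, low = 0.5, high = 45, fs = NULL, order = 4,
                     pad_s = 1) {
  if (inherits(x, "trial_set")) {
    out <- x
    out$data <- apply_series(x$data, function(s)
      bandpass(s, low, high, x$fs, order, pad_s))
    return(out)
  }
  if (is.null(fs)) stop_param("`fs` required for a plain series")
  if (!(low > 0 && low < high && high < fs / 2))
    stop_param("need 0 < low < high < fs/2 (got %g, %g at fs = %g)",
               low, high, fs)
  des <- butter_design(order, c(low, high) / (fs / 2), "pass")
  pad <- as.integer(round(pad_s * fs))
  if (length(x) <= pad + 1) stop_param("series too short for band-pass")
  filtfilt_reflect(des$b, des$a, x, pad = pad)
}

# apply a series -> series function over the sample axis of a 3-d array
apply_series <- function(a, f) {
  d <- dim(a)
  out <- a
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    out[i, j, ] <- f(a[i, j, ])
  out
}

#' Anti-aliased downsampling to a target rate
#'
#' @param x Numeric series or [trial_set].
#' @param fs_in Input rate (Hz); from the `trial_set` if given one.
#' @param fs_out Target rate (Hz), `fs_out <= fs_in`, ratio rational.
#' @return Downsampled object; a `trial_set` keeps its event alignment
#'   (`time0_index` is rescaled).
#' @export
downsample <- function(x, fs_in = NULL, fs_out = 128) {
  if (inherits(x, "trial_set")) {
    n_out <- round(dim(x$data)[3] * fs_out / x$fs)
    d <- dim(x$data)
    out <- array(NA_real_, c(d[1], d[2], n_out))
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
      out[i, j, ] <- resample_series(x$data[i, j, ], x$fs, fs_out)
    return(trial_set(out, fs_out,
                     as.integer(round((x$time0_index - 1) * fs_out / x$fs)) + 1L,
                     x$condition, x$channels))
  }
  if (is.null(fs_in)) stop_param("`fs_in` required for a plain series")
  resample_series(x, fs_in, fs_out)
}

#' Extract causal sliding windows from a trial_set
#'
#' Windows of `window_s` seconds stepped by `step_s`; the window reported
#' at end time t spans \[t - window_s, t\]. The first window ends
#' `window_s` after trial start. With `taper = "hanning"` each window is
#' multiplied by a Hanning function of its length (used before per-window
#' DFA/ARFIMA to avoid edge effects); stitching uses untapered windows.
#'
#' @param ts A [trial_set].
#' @param window_s Window length (s), default 2.
#' @param step_s Step (s), default 0.1.
#' @param taper `"hanning"` or `"none"`.
#' @return A [window_series].
#' @export
sliding_windows <- function(ts, window_s = 2, step_s = 0.1,
                            taper = c("hanning", "none")) {
  taper <- match.arg(taper)
  stopifnot(inherits(ts, "trial_set"))
  d <- dim(ts$data)
  n_samp <- d[3]
  wlen <- as.integer(round(window_s * ts$fs))
  step <- step_s * ts$fs
  if (wlen > n_samp) stop_param("window (%g s) longer than trial", window_s)
  starts <- seq(0, n_samp - wlen, by = step)
  starts <- as.integer(round(starts)) + 1L
  n_win <- length(starts)
  tap <- if (taper == "hanning") hanning(wlen) else rep(1, wlen)
  w <- array(NA_real_, c(d[1], d[2], n_win, wlen))
  for (k in seq_len(n_win)) {
    idx <- starts[k]:(starts[k] + wlen - 1L)
    for (j in seq_len(d[2]))
      w[, j, k, ] <- sweep(ts$data[, j, idx, drop = FALSE][, 1, ],
                           2, tap, "*")
  }
  end_times <- (starts + wlen - 1L - ts$time0_index) / ts$fs
  window_series(w, end_times, window_s, step_s, ts$fs, taper,
                ts$condition, ts$channels)
}

#' Alpha-band amplitude envelope of a trial_set
#'
#' Band-passes each trial/channel 8–13 Hz (same zero-phase Butterworth
#' design) and takes the magnitude of the analytic signal (FFT Hilbert
#' transform) over the full trial, so envelope edge effects are confined to
#' the trial edges.
#'
#' @param ts A [trial_set].
#' @param low,high Alpha band edges (Hz).
#' @param order Butterworth order.
#' @return An envelope-valued `trial_set` (all values >= 0).
#' @export
alpha_envelope <- function(ts, low = 8, high = 13, order = 4) {
  stopifnot(inherits(ts, "trial_set"))
  if (ts$fs <= 2 * high) stop_param("fs must exceed twice the band edge")
  out <- ts
  out$data <- apply_series(ts$data, function(s)
    hilbert_envelope(bandpass(s, low, high, ts$fs, order)))
  out
}

#' Stitch the time-aligned window from every trial into one long segment
#'
#' Concatenates, in trial order, the (untapered) window at the given end
#' time from every trial of a [window_series], enabling DFA on timescales
#' far beyond a single trial. 40 trials of 2 s windows give an 80 s
#' segment; 22 trials give 44 s.
#'
#' @param ws A [window_series] (build it with `taper = "none"`).
#' @param window_end_time Window end time (s) on the series' grid.
#' @param channel Channel label or index.
#' @param content Content tag for the result.
#' @return A [stitched_segment].
#' @export
stitch <- function(ws, window_end_time, channel,
                   content = c("broadband", "alpha_envelope")) {
  content <- match.arg(content)
  stopifnot(inherits(ws, "window_series"))
  if (dim(ws$windows)[1] < 2) stop_param("need >= 2 trials to stitch")
  if (ws$taper != "none")
    warning("stitching tapered windows zeroes the seams; use taper = 'none'")
  k <- which(abs(ws$window_end_times - window_end_time) < ws$step_s / 4)
  if (length(k) != 1L)
    stop_param("window end time %g s not on the grid", window_end_time)
  ch <- if (is.character(channel)) match(channel, ws$channels) else channel
  if (is.na(ch) || ch < 1 || ch > dim(ws$windows)[2])
    stop_param("unknown channel")
  seg <- as.numeric(t(ws$windows[, ch, k, ]))
  stitched_segment(seg, ws$fs, ws$window_end_times[k],
                   dim(ws$windows)[1], content)
}

#' Exponential smoothing of a feature sequence
#'
#' \eqn{s_1 = v_1}; \eqn{s_k = \alpha v_k + (1-\alpha) s_{k-1}}. `NA`
#' values are carried through: the state is held and the output marked
#' missing.
#'
#' @param values Numeric sequence.
#' @param alpha_smooth Smoothing constant in (0, 1\]; 1 = no smoothing.
#' @return Smoothed sequence, same length.
#' @export
exp_smooth <- function(values, alpha_smooth = 0.3) {
  assert_scalar_in(alpha_smooth, "alpha_smooth", 0, 1, lower_open = TRUE)
  out <- values
  state <- NA_real_
  for (k in seq_along(values)) {
    v <- values[k]
    if (is.na(v)) { out[k] <- NA_real_; next }
    state <- if (is.na(state)) v else alpha_smooth * v + (1 - alpha_smooth) * state
    out[k] <- state
  }
  out
}
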