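# Core S3 containers: trial_set, window_series, stitched_segment.

#' Trial-segmented multichannel EEG container
#'
#' @param data Numeric array, trials x channels x samples.
#' @param fs Sampling rate (Hz).
#' @param time0_index 1-based sample index of the event (onset or cue).
#' @param condition Character vector of per-trial condition labels.
#' @param channels Character vector of channel labels (e.g. C3, Cz, C4).
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(data, fs, time0_index, condition, channels) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (fs <= 0) stop_param("`fs` must be positive")
  if (time0_index < 1 || time0_index > dim(data)[3])
    stop_param("`time0_index` outside trial bounds")
  if (length(condition) != dim(data)[1])
    stop_param("one condition label per trial required")
  if (length(channels) != dim(data)[2])
    stop_param("one channel label per channel required")
  structure(list(data = data, fs = fs,
                 time0_index = as.integer(time0_index),
                 condition = as.character(condition),
                 channels = as.character(channels)),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("trial_set: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  cat("  conditions:", paste(sprintf("%s (%d)", names(table(x$condition)),
                                     table(x$condition)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Time axis of a trial_set in seconds relative to the event
#' @param ts A `trial_set`.
#' @return Numeric vector, one entry per sample.
#' @export
trial_time <- function(ts) {
  (seq_len(dim(ts$data)[3]) - ts$time0_index) / ts$fs
}

#' Subset a trial_set by condition
#' @param ts A `trial_set`.
#' @param condition Condition label(s) to keep.
#' @return A `trial_set` containing only the matching trials.
#' @export
subset_condition <- function(ts, condition) {
  keep <- ts$condition %in% condition
  if (!any(keep)) stop_param("no trials with condition %s",
                             paste(condition, collapse = "/"))
  trial_set(ts$data[keep, , , drop = FALSE], ts$fs, ts$time0_index,
            ts$condition[keep], ts$channels)
}

#' Sequence of causal sliding windows extracted from a trial_set
#'
#' Windows are labelled by their causal END time: the window reported at
#' time t spans \[t - window, t\] seconds.
#'
#' @param windows Array, trials x channels x n_windows x window_samples.
#' @param window_end_times End times (s relative to the event).
#' @param window_s,step_s Window length and step (s).
#' @param fs Sampling rate (Hz).
#' @param taper `"hanning"` or `"none"`.
#' @param condition Per-trial condition labels.
#' @param channels Channel labels.
#' @return An object of class `window_series`.
#' @export
window_series <- function(windows, window_end_times, window_s, step_s, fs,
                          taper, condition, channels) {
  stopifnot(is.array(windows), length(dim(windows)) == 4L,
            dim(windows)[3] == length(window_end_times))
  structure(list(windows = windows, window_end_times = window_end_times,
                 window_s = window_s, step_s = step_s, fs = fs,
                 taper = taper, condition = condition, channels = channels),
            class = "window_series")
}

#' @export
print.window_series <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf(
    "window_series: %d trials x %d channels x %d windows x %d samples\n",
    d[1], d[2], d[3], d[4]))
  cat(sprintf("  %g s windows, %g s step, taper = %s, ends %g..%g s\n",
              x$window_s, x$step_s, x$taper,
              min(x$window_end_times), max(x$window_end_times)))
  invisible(x)
}

#' Long segment stitched from time-aligned windows across trials
#'
#' @param series Numeric vector (concatenated windows).
#' @param fs Sampling rate (Hz).
#' @param window_end_time Source window end time (s).
#' @param n_trials_stitched Number of trials concatenated.
#' @param content `"broadband"` or `"alpha_envelope"`.
#' @return An object of class `stitched_segment`.
#' @export
stitched_segment <- function(series, fs, window_end_time, n_trials_stitched,
                             content = c("broadband", "alpha_envelope")) {
  content <- match.arg(content)
  structure(list(series = as.numeric(series), fs = fs,
                 window_end_time = window_end_time,
                 n_trials_stitched = as.integer(n_trials_stitched),
                 content = content),
            class = "stitched_segment")
}

#' @export
print.stitched_segment <- function(x, ...) {
  cat(sprintf(
    "stitched_segment (%s): %d samples = %g s from %d trials at t = %g s\n",
    x$content, length(x$series), length(x$series) / x$fs,
    x$n_trials_stitched, x$window_end_time))
  invisible(x)
}
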