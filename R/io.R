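# Readers and writers: delimited long-format trial tables with a JSON
# ground-truth/metadata sidecar, tidy CSV results, and a minimal plain-EDF
# (16-bit) writer/reader (one data record per trial). EDF+ annotation
# parsing is not implemented; events travel in the JSON sidecar.

#' Write a trial_set as a delimited long-format table
#'
#' Columns: `trial`, `condition`, `channel`, `sample_index` (0-based),
#' `value`. A JSON sidecar `<path>.json` records `fs`, `time0_index`,
#' channel order, condition labels and any ground truth supplied.
#'
#' @param ts A [trial_set].
#' @param path Output CSV path.
#' @param truth Optional ground-truth list (stored in the sidecar).
#' @return `path`, invisibly.
#' @export
write_trialset_csv <- function(ts, path, truth = NULL) {
  stopifnot(inherits(ts, "trial_set"))
  d <- dim(ts$data)
  df <- data.frame(
    trial = rep(seq_len(d[1]), each = d[2] * d[3]),
    condition = rep(ts$condition, each = d[2] * d[3]),
    channel = rep(rep(ts$channels, each = d[3]), times = d[1]),
    sample_index = rep(0:(d[3] - 1L), times = d[1] * d[2]),
    value = as.numeric(aperm(ts$data, c(3, 2, 1))))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(fs = ts$fs, time0_index = ts$time0_index,
               channels = ts$channels, condition = ts$condition,
               n_trials = d[1], n_samples = d[3])
  if (!is.null(truth)) meta$truth <- truth
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a delimited long-format trial table back into a trial_set
#'
#' @param path CSV path written by [write_trialset_csv] (the `.json`
#'   sidecar must sit next to it).
#' @param channels Channel labels to keep (default: all present). A
#'   requested label that is absent raises an error naming it.
#' @return List: `trials` (a [trial_set]), `truth` (or NULL).
#' @export
read_trialset_csv <- function(path, channels = NULL) {
  if (!file.exists(path)) stop_param("no such file: %s", path)
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop_param("missing sidecar: %s", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- utils::read.csv(path)
  need <- c("trial", "channel", "sample_index", "value")
  if (!all(need %in% names(df)))
    stop_param("malformed table: need columns %s", paste(need, collapse = ", "))
  present <- unique(df$channel)
  if (is.null(channels)) channels <- meta$channels
  missing_ch <- setdiff(channels, present)
  if (length(missing_ch))
    stop_param("channel(s) not in file: %s", paste(missing_ch, collapse = ", "))
  trials <- sort(unique(df$trial))
  n_samp <- meta$n_samples
  data <- array(NA_real_, c(length(trials), length(channels), n_samp))
  for (i in seq_along(trials)) for (j in seq_along(channels)) {
    sel <- df$trial == trials[i] & df$channel == channels[j]
    v <- df$value[sel][order(df$sample_index[sel])]
    data[i, j, ] <- v
  }
  ts <- trial_set(data, meta$fs, meta$time0_index,
                  meta$condition, channels)
  list(trials = ts, truth = meta$truth)
}

# ---- minimal EDF -----------------------------------------------------------

pad_field <- function(x, width) {
  s <- substr(format(x, scientific = FALSE, trim = TRUE), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a trial_set to a minimal EDF file
#'
#' Plain EDF (not EDF+): 16-bit integers, one data record per trial, so
#' trial boundaries align with record boundaries. Physical scaling covers
#' the observed amplitude range per channel. Event timing and condition
#' labels go to a JSON sidecar `<path>.json` (no TAL annotations).
#'
#' @param ts A [trial_set].
#' @param path Output `.edf` path.
#' @param truth Optional ground truth for the sidecar.
#' @return `path`, invisibly.
#' @export
write_edf <- function(ts, path, truth = NULL) {
  stopifnot(inherits(ts, "trial_set"))
  d <- dim(ts$data)
  ns <- d[2]
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(paste0(pad_field(x, width)),
                                     con, nchars = width, eos = NULL)
  wr("0", 8)                       # version
  wr("synthetic", 80)              # patient id (synthetic data)
  wr("lrtceeg", 80)                # recording id
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8)            # header bytes
  wr("", 44)
  wr(d[1], 8)                      # n data records = n trials
  wr(d[3] / ts$fs, 8)              # record duration (s)
  wr(ns, 4)
  phys_min <- apply(ts$data, 2, min); phys_max <- apply(ts$data, 2, max)
  span <- pmax(phys_max - phys_min, 1e-6)
  for (j in seq_len(ns)) wr(ts$channels[j], 16)
  for (j in seq_len(ns)) wr("synthetic EEG", 80)
  for (j in seq_len(ns)) wr("uV", 8)
  for (j in seq_len(ns)) wr(sprintf("%.6g", phys_min[j]), 8)
  for (j in seq_len(ns)) wr(sprintf("%.6g", phys_max[j]), 8)
  for (j in seq_len(ns)) wr(-32768, 8)
  for (j in seq_len(ns)) wr(32767, 8)
  for (j in seq_len(ns)) wr("", 80)
  for (j in seq_len(ns)) wr(d[3], 8)   # samples per record
  for (j in seq_len(ns)) wr("", 32)
  for (i in seq_len(d[1])) for (j in seq_len(ns)) {
    dig <- as.integer(round((ts$data[i, j, ] - phys_min[j]) / span[j] *
                              65535 - 32768))
    writeBin(dig, con, size = 2, endian = "little")
  }
  meta <- list(fs = ts$fs, time0_index = ts$time0_index,
               condition = ts$condition, channels = ts$channels)
  if (!is.null(truth)) meta$truth <- truth
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a minimal EDF file written by [write_edf]
#'
#' @param path `.edf` path (JSON sidecar `<path>.json` supplies event
#'   timing and condition labels when present).
#' @param channels Channel labels to keep; absent labels raise an error.
#' @return List: `trials` (a [trial_set]), `truth` (or NULL).
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) stop_param("no such file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(j) rd(16), character(1))
  for (j in seq_len(ns)) rd(80)
  for (j in seq_len(ns)) rd(8)
  phys_min <- as.numeric(vapply(seq_len(ns), function(j) rd(8), character(1)))
  phys_max <- as.numeric(vapply(seq_len(ns), function(j) rd(8), character(1)))
  dig_min <- as.numeric(vapply(seq_len(ns), function(j) rd(8), character(1)))
  dig_max <- as.numeric(vapply(seq_len(ns), function(j) rd(8), character(1)))
  for (j in seq_len(ns)) rd(80)
  n_samp <- as.integer(vapply(seq_len(ns), function(j) rd(8), character(1)))
  for (j in seq_len(ns)) rd(32)
  if (length(unique(n_samp)) != 1L)
    stop_param("mixed per-channel sample counts not supported")
  fs <- n_samp[1] / rec_dur
  data <- array(NA_real_, c(n_rec, ns, n_samp[1]))
  for (i in seq_len(n_rec)) for (j in seq_len(ns)) {
    dig <- readBin(con, integer(), n = n_samp[j], size = 2,
                   endian = "little")
    data[i, j, ] <- phys_min[j] + (dig - dig_min[j]) /
      (dig_max[j] - dig_min[j]) * (phys_max[j] - phys_min[j])
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else NULL
  condition <- if (!is.null(meta)) meta$condition else rep("unknown", n_rec)
  time0 <- if (!is.null(meta)) meta$time0_index else 1L
  if (is.null(channels)) channels <- labels
  missing_ch <- setdiff(channels, labels)
  if (length(missing_ch))
    stop_param("channel(s) not in file: %s", paste(missing_ch, collapse = ", "))
  keep <- match(channels, labels)
  ts <- trial_set(data[, keep, , drop = FALSE], fs, time0, condition,
                  channels)
  list(trials = ts, truth = if (!is.null(meta)) meta$truth else NULL)
}

#' Read a recording in either supported format
#'
#' @param path File path; format inferred from the extension unless given.
#' @param format `"edf"` or `"delimited"`.
#' @param channels Channel labels to keep.
#' @return List: `trials`, `truth`.
#' @export
read_recording <- function(path, format = c("auto", "edf", "delimited"),
                           channels = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
  else "delimited"
  if (format == "edf") read_edf(path, channels)
  else read_trialset_csv(path, channels)
}

#' Write a feature time course as tidy CSV
#'
#' Columns: `trial`, `condition`, `channel`, `window_end_time`, `value`
#' (plus `r_squared` when available).
#'
#' @param tc A [feature_timecourse].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(tc, path) {
  stopifnot(inherits(tc, "feature_timecourse"))
  d <- dim(tc$values)
  df <- data.frame(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    condition = rep(tc$condition, times = d[2] * d[3]),
    channel = rep(rep(tc$channels, each = d[1]), times = d[3]),
    window_end_time = rep(tc$window_end_times, each = d[1] * d[2]),
    value = as.numeric(tc$values))
  if (!is.null(tc$r_squared)) df$r_squared <- as.numeric(tc$r_squared)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
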