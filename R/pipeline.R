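# Configuration handling and the end-to-end pipeline:
# simulate -> prep -> lrtc -> validate -> stats -> classify.

#' Default pipeline configuration
#'
#' All stage parameters with defaults equal to the package's standard
#' analysis settings: 0.5-45 Hz band (order-4 zero-phase Butterworth),
#' 128 Hz target rate, 2 s Hanning windows at 100 ms steps, 25 box sizes
#' in \[10, N/4\], exponential smoothing 0.3, 8-13 Hz alpha band with
#' 2-20 s stitched timescales, AR orders 1-10, Mann-Whitney per-window
#' tests at 0.05, 10 x 10-fold CV.
#'
#' @param ... Named overrides for any default.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    band_low = 0.5, band_high = 45, filter_order = 4,
    fs_target = 128,
    window_s = 2, step_s = 0.1, taper = "hanning",
    n_min = 10, k_sizes = 25, alpha_smooth = 0.3,
    alpha_low = 8, alpha_high = 13,
    stitch_timescales = c(2, 20),
    stitch_bb_timescales = c(0.1, 2),
    p_range = 1:10,
    stat_alpha = 0.05, stat_test = "mann_whitney",
    cv_folds = 10, cv_reps = 10,
    validate_n_windows = 40,
    seed = 1,
    synth = list()      # overrides passed to synthetic_spec()
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop_param("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$band_low > 0, cfg$band_low < cfg$band_high,
            cfg$band_high < cfg$fs_target / 2,
            cfg$window_s > 0, cfg$step_s > 0,
            cfg$alpha_smooth > 0, cfg$alpha_smooth <= 1)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON (or YAML if available)
#'
#' Unknown keys are rejected.
#'
#' @param path Path to a `.json` (or `.yaml`/`.yml`, when the `yaml`
#'   package is installed) config file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_param("YAML config requires the yaml package; use JSON")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Run the full analysis chain on a synthetic dataset
#'
#' Generates a dataset from `cfg$synth`, band-passes it, extracts tapered
#' sliding windows and broadband H time courses, runs the validation
#' cascade on a window subsample, computes task-vs-rest significance per
#' channel, stitches alpha-envelope and broadband segments for
#' long-timescale exponents, and classifies task vs rest per window.
#' Every intermediate is written under `out_dir` together with a JSON
#' manifest (config, seed, package version), making the bundle
#' reproducible from the manifest alone.
#'
#' @param cfg A [pipeline_config].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every stage result.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- do.call(synthetic_spec,
                  c(cfg$synth, list(seed = cfg$seed)))
  ds <- gen_dataset(spec)

  filt <- bandpass(ds$trials, cfg$band_low, cfg$band_high,
                   order = cfg$filter_order)
  ws <- sliding_windows(filt, cfg$window_s, cfg$step_s, taper = cfg$taper)
  tc <- h_timecourse(ws, cfg$alpha_smooth, cfg$n_min, cfg$k_sizes)
  tc_task <- subset_timecourse(tc, "task")
  tc_rest <- subset_timecourse(tc, "rest")
  write_timecourse_csv(tc, file.path(out_dir, "h_bb_timecourse.csv"))

  # validation cascade on an evenly spaced subsample of task windows
  # (untapered: validate_lrtc tapers internally for its DFA stages)
  ws_raw <- sliding_windows(filt, cfg$window_s, cfg$step_s, taper = "none")
  val <- NULL
  if (cfg$validate_n_windows >= 20) {
    wt <- ws_raw$windows[ws_raw$condition == "task", 1, , , drop = FALSE]
    n_avail <- dim(wt)[1] * dim(wt)[3]
    idx <- unique(round(seq(1, n_avail, length.out =
                              min(cfg$validate_n_windows, n_avail))))
    flat <- matrix(aperm(wt[, 1, , , drop = FALSE], c(1, 3, 2, 4)),
                   nrow = n_avail, byrow = FALSE)
    val <- validate_lrtc(lapply(idx, function(i) flat[i, ]),
                         seed = cfg$seed, p_range = cfg$p_range)
  }

  sig <- lapply(seq_along(tc$channels), function(ch)
    significance_timecourse(tc_task, tc_rest, ch, cfg$stat_alpha,
                            cfg$stat_test))
  names(sig) <- tc$channels
  sig_df <- data.frame(
    channel = rep(tc$channels, each = length(tc$window_end_times)),
    window_end_time = rep(tc$window_end_times, times = length(tc$channels)),
    p_value = unlist(lapply(sig, `[[`, "p_values")))
  utils::write.csv(sig_df, file.path(out_dir, "significance.csv"),
                   row.names = FALSE)

  # stitched alpha-envelope and broadband exponents per window (C3)
  env <- alpha_envelope(filt, cfg$alpha_low, cfg$alpha_high,
                        cfg$filter_order)
  ws_env <- sliding_windows(env, cfg$window_s, cfg$step_s, taper = "none")
  ws_bb <- ws_raw
  tmax <- pmin(cfg$stitch_timescales[2],
               spec$n_trials_per_condition * cfg$window_s / 4)
  bounds_alpha <- c(cfg$stitch_timescales[1], tmax)
  stitch_h <- function(wsx, cond, content, bounds) vapply(
    wsx$window_end_times, function(t0) {
      keep <- wsx$condition == cond
      sub <- window_series(wsx$windows[keep, , , , drop = FALSE],
                           wsx$window_end_times, wsx$window_s, wsx$step_s,
                           wsx$fs, wsx$taper, wsx$condition[keep],
                           wsx$channels)
      stitched_dfa(stitch(sub, t0, 1, content), bounds)$H
    }, numeric(1))
  h_alpha_task <- stitch_h(ws_env, "task", "alpha_envelope", bounds_alpha)
  h_alpha_rest <- stitch_h(ws_env, "rest", "alpha_envelope", bounds_alpha)
  # broadband exponents on stitched segments are valid below the ~2 s
  # crossover (the 0.5 Hz high-pass suppresses slower fluctuations), so
  # they use the short-timescale bounds
  h_bb_task <- stitch_h(ws_bb, "task", "broadband",
                        cfg$stitch_bb_timescales)
  h_bb_rest <- stitch_h(ws_bb, "rest", "broadband",
                        cfg$stitch_bb_timescales)
  utils::write.csv(
    data.frame(window_end_time = ws_env$window_end_times,
               h_alpha_task = h_alpha_task, h_alpha_rest = h_alpha_rest,
               h_bb_task = h_bb_task, h_bb_rest = h_bb_rest),
    file.path(out_dir, "stitched_exponents.csv"), row.names = FALSE)

  ctc <- within_subject_cv(tc_task, tc_rest, folds = cfg$cv_folds,
                           reps = cfg$cv_reps, alpha = cfg$stat_alpha,
                           seed = cfg$seed)
  times <- detect_times(ctc, event_time = 0)
  utils::write.csv(
    data.frame(window_end_time = ctc$window_end_times,
               accuracy = ctc$accuracy, f1 = ctc$f1),
    file.path(out_dir, "classification.csv"), row.names = FALSE)

  manifest <- list(
    package = "lrtceeg",
    version = as.character(utils::packageVersion("lrtceeg")),
    seed = cfg$seed, config = unclass(cfg),
    summary = list(
      surrogate_p = if (!is.null(val)) val$surrogate$p_value,
      pct_arfima = if (!is.null(val))
        val$arfima_comparison$pct_arfima_preferred,
      pct_mldfa_linear = if (!is.null(val)) val$mldfa_pct_linear,
      mean_r_squared = if (!is.null(val)) val$mean_r_squared,
      peak_accuracy = ctc$peak_accuracy,
      peak_time = ctc$peak_time,
      crossing_time = times$crossing_time,
      lead_time = times$lead_time,
      threshold = ctc$threshold))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dataset = ds, windows = ws, timecourse = tc,
                 validation = val, significance = sig,
                 stitched = list(h_alpha_task = h_alpha_task,
                                 h_alpha_rest = h_alpha_rest,
                                 h_bb_task = h_bb_task,
                                 h_bb_rest = h_bb_rest),
                 classifier = ctc, detect = times, manifest = manifest,
                 out_dir = out_dir))
}

#' Subset a feature_timecourse by condition
#' @param tc A [feature_timecourse].
#' @param condition Condition label(s) to keep.
#' @return A `feature_timecourse` with only the matching trials.
#' @export
subset_timecourse <- function(tc, condition) {
  keep <- tc$condition %in% condition
  if (!any(keep)) stop_param("no trials with condition %s",
                             paste(condition, collapse = "/"))
  feature_timecourse(tc$values[keep, , , drop = FALSE],
                     tc$window_end_times, tc$condition[keep], tc$channels,
                     r_squared = if (!is.null(tc$r_squared))
                       tc$r_squared[keep, , , drop = FALSE])
}
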