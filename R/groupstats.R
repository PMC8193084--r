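# Group-level statistics on feature time courses: grand averages,
# normality-gated test choice, per-window significance periods, and the
# correlation between broadband and alpha-envelope exponent time courses.

#' Grand average (mean and SD over trials) of a feature time course
#'
#' @param tc A [feature_timecourse] (>= 2 trials). Missing values are
#'   excluded per window.
#' @return List: `mean` and `sd` (channels x windows matrices),
#'   `window_end_times`, `channels`, `n` (contributing trials per cell).
#' @export
grand_average <- function(tc) {
  stopifnot(inherits(tc, "feature_timecourse"))
  if (dim(tc$values)[1] < 2) stop_param("need >= 2 trials")
  mn <- apply(tc$values, c(2, 3), mean, na.rm = TRUE)
  sd_ <- apply(tc$values, c(2, 3), stats::sd, na.rm = TRUE)
  n <- apply(tc$values, c(2, 3), function(v) sum(!is.na(v)))
  mn[n == 0] <- NA_real_
  if (any(n == 0))
    warning(sprintf("%d all-missing cell(s) in grand average", sum(n == 0)))
  rownames(mn) <- rownames(sd_) <- rownames(n) <- tc$channels
  list(mean = mn, sd = sd_, n = n,
       window_end_times = tc$window_end_times, channels = tc$channels)
}

#' Normality-gated choice between t-test and Mann-Whitney
#'
#' Both samples are screened with a one-sample Kolmogorov-Smirnov test
#' against a normal with mean and SD estimated from the sample
#' (Lilliefors-style; the estimated-parameter caveat is accepted). If both
#' pass at `alpha`, the two-sample t-test is chosen; otherwise the
#' two-sided Mann-Whitney U test.
#'
#' @param samples_a,samples_b Numeric samples, >= 5 values each.
#' @param alpha Normality screening level (default 0.05).
#' @return `"t_test"` or `"mann_whitney"`.
#' @export
choose_test <- function(samples_a, samples_b, alpha = 0.05) {
  a <- samples_a[!is.na(samples_a)]
  b <- samples_b[!is.na(samples_b)]
  if (length(a) < 5 || length(b) < 5)
    stop_param("need >= 5 samples per group")
  normal <- function(x) suppressWarnings(
    stats::ks.test(x, "pnorm", mean = mean(x), sd = stats::sd(x))$p.value
  ) > alpha
  if (normal(a) && normal(b)) "t_test" else "mann_whitney"
}

# two-sided p-value for the chosen test
run_test <- function(a, b, test) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  if (test == "t_test") stats::t.test(a, b)$p.value
  else suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
}

#' Per-window significance time course between two conditions
#'
#' Runs a two-sided per-window test over trials between two aligned
#' feature time courses (one channel at a time) and reports the longest
#' contiguous run of `p < alpha` as the significant interval. By default
#' the test is the Mann-Whitney U test (matching per-window reporting on
#' H time courses); `test = "auto"` gates the choice per window via
#' [choose_test]. No multiple-comparison correction is applied unless
#' `p_adjust` is set (e.g. `"BH"`).
#'
#' @param task,rest Two [feature_timecourse]s on identical window grids.
#' @param channel Channel label or index.
#' @param alpha Significance level (default 0.05).
#' @param test `"mann_whitney"`, `"t_test"`, or `"auto"`.
#' @param p_adjust Method for [stats::p.adjust], or `"none"`.
#' @return List of class `significance_timecourse`: `p_values`,
#'   `test_used`, `significant_interval` (start/end window end times, or
#'   NAs), `significant_mask`, `window_end_times`.
#' @export
significance_timecourse <- function(task, rest, channel = 1, alpha = 0.05,
                                    test = c("mann_whitney", "t_test",
                                             "auto"),
                                    p_adjust = "none") {
  test <- match.arg(test)
  stopifnot(inherits(task, "feature_timecourse"),
            inherits(rest, "feature_timecourse"))
  if (length(task$window_end_times) != length(rest$window_end_times) ||
      any(abs(task$window_end_times - rest$window_end_times) > 1e-9))
    stop_param("window grids are not aligned")
  ch_t <- if (is.character(channel)) match(channel, task$channels) else channel
  ch_r <- if (is.character(channel)) match(channel, rest$channels) else channel
  n_win <- length(task$window_end_times)
  p <- rep(NA_real_, n_win)
  used <- character(n_win)
  for (k in seq_len(n_win)) {
    a <- task$values[, ch_t, k]
    b <- rest$values[, ch_r, k]
    tk <- if (test == "auto") choose_test(a, b) else test
    used[k] <- tk
    p[k] <- run_test(a, b, tk)
  }
  if (p_adjust != "none") p <- stats::p.adjust(p, method = p_adjust)
  sig <- !is.na(p) & p < alpha
  interval <- c(NA_real_, NA_real_)
  if (any(sig)) {
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    interval <- task$window_end_times[c(starts[best], ends[best])]
  }
  structure(list(p_values = p, test_used = used,
                 significant_interval = interval, significant_mask = sig,
                 window_end_times = task$window_end_times),
            class = "significance_timecourse")
}

#' @export
print.significance_timecourse <- function(x, ...) {
  cat(sprintf("significance_timecourse: %d/%d windows significant",
              sum(x$significant_mask), length(x$p_values)))
  if (!is.na(x$significant_interval[1]))
    cat(sprintf("; longest run %g..%g s", x$significant_interval[1],
                x$significant_interval[2]))
  cat("\n")
  invisible(x)
}

#' Correlation between broadband and alpha-envelope exponent time courses
#'
#' Pearson correlation between two aligned per-window stitched-exponent
#' sequences (H_BB and H_alpha). During motor tasks the broadband increase
#' and alpha-envelope decrease make this strongly negative; at rest the
#' two are uncorrelated.
#'
#' @param hbb,halpha Equal-length numeric sequences (>= 10 windows).
#' @return Pearson correlation coefficient, or `NA` (with a warning) if
#'   either sequence has zero variance.
#' @export
hbb_halpha_correlation <- function(hbb, halpha) {
  if (length(hbb) != length(halpha)) stop_param("sequences differ in length")
  ok <- !is.na(hbb) & !is.na(halpha)
  if (sum(ok) < 10) stop_param("need >= 10 aligned windows")
  if (stats::var(hbb[ok]) == 0 || stats::var(halpha[ok]) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(hbb[ok], halpha[ok])
}
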