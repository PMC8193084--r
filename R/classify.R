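# Per-window binary classification of motor task vs rest from the
# 3-channel Hurst-exponent features: pooled-covariance LDA, 10 x 10-fold
# within-subject cross-validation, leave-one-participant-out CV, exact
# binomial chance thresholds, and detection-time extraction.

#' Train a binary linear discriminant (pooled covariance)
#'
#' Classic two-class LDA: class means, pooled within-class covariance,
#' discriminant direction `w = S^{-1} (mu1 - mu0)` with the threshold at
#' the projected midpoint (equal priors; class sizes are balanced by
#' construction upstream). A singular pooled covariance triggers a
#' shrinkage fallback toward its diagonal, and that fallback is flagged.
#'
#' @param features Numeric matrix, samples x features.
#' @param labels Binary labels (factor/character/logical); the second
#'   level is the positive class.
#' @return List of class `lda_model`: `w`, `threshold`, `levels`,
#'   `shrunk`.
#' @export
lda_train <- function(features, labels) {
  features <- as.matrix(features)
  f <- factor(labels)
  if (nlevels(f) != 2) stop_param("need exactly two classes")
  if (min(table(f)) < 4) stop_param("need >= 4 samples per class")
  x0 <- features[f == levels(f)[1], , drop = FALSE]
  x1 <- features[f == levels(f)[2], , drop = FALSE]
  m0 <- colMeans(x0); m1 <- colMeans(x1)
  S <- ((nrow(x0) - 1) * stats::cov(x0) + (nrow(x1) - 1) * stats::cov(x1)) /
    (nrow(x0) + nrow(x1) - 2)
  shrunk <- FALSE
  w <- tryCatch(solve(S, m1 - m0), error = function(e) NULL)
  if (is.null(w) || any(!is.finite(w))) {
    shrunk <- TRUE
    lam <- 0.1
    Sr <- (1 - lam) * S + lam * diag(diag(S) + 1e-8, nrow(S))
    w <- solve(Sr, m1 - m0)
  }
  structure(list(w = w, threshold = sum(w * (m0 + m1) / 2),
                 levels = levels(f), shrunk = shrunk),
            class = "lda_model")
}

#' Predict class labels from an LDA model
#'
#' @param object An `lda_model`.
#' @param newdata Numeric matrix, samples x features.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  score <- as.matrix(newdata) %*% object$w
  object$levels[(score > object$threshold) + 1L]
}

# accuracy (%) and F1 for the positive class
acc_f1 <- function(truth, pred, positive) {
  acc <- 100 * mean(truth == pred)
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  c(acc = acc, f1 = f1)
}

# stratified k-fold assignment (a permutation within each class)
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

#' Exact binomial chance-level accuracy threshold
#'
#' The smallest accuracy exceeding chance at the given level for a
#' balanced binary problem: the smallest k with
#' `P(X >= k | Binomial(n_trials, 0.5)) <= alpha`, returned as
#' `100 k / n_trials` percent.
#'
#' @param n_trials Number of trials (>= 10).
#' @param alpha Significance level (default 0.05 for the 95% bound).
#' @return Threshold accuracy in percent.
#' @export
binomial_threshold <- function(n_trials, alpha = 0.05) {
  if (n_trials < 10) stop_param("need n_trials >= 10")
  k <- stats::qbinom(alpha, n_trials, 0.5, lower.tail = FALSE)
  # qbinom gives smallest k with P(X > k) <= alpha; we need P(X >= k) <= alpha
  if (stats::pbinom(k - 1, n_trials, 0.5, lower.tail = FALSE) > alpha)
    k <- k + 1L
  100 * k / n_trials
}

#' Within-subject repeated k-fold CV classification time course
#'
#' For each sliding window, H features from the task trials and an
#' equally sized random subsample of the rest trials (redrawn each
#' repetition, seeded) are classified with LDA under repeated stratified
#' k-fold cross-validation. Reports per-window accuracy (%) and F1 (task
#' class positive), the exact binomial chance threshold, peak accuracy and
#' time, and the first threshold crossing.
#'
#' @param tc_task,tc_rest [feature_timecourse]s on identical grids.
#' @param channels Channel indices/labels used as features (default all).
#' @param folds,reps CV folds and repetitions (default 10 x 10).
#' @param alpha Level for the binomial threshold.
#' @param seed RNG seed controlling subsampling and fold assignment.
#' @return Object of class `classifier_timecourse`: `accuracy`, `f1`,
#'   `threshold`, `window_end_times`, `peak_accuracy`, `peak_time`,
#'   `crossing_time`.
#' @export
within_subject_cv <- function(tc_task, tc_rest, channels = NULL,
                              folds = 10, reps = 10, alpha = 0.05,
                              seed = 1) {
  stopifnot(inherits(tc_task, "feature_timecourse"),
            inherits(tc_rest, "feature_timecourse"))
  if (length(tc_task$window_end_times) != length(tc_rest$window_end_times))
    stop_param("window grids are not aligned")
  if (is.null(channels)) channels <- seq_along(tc_task$channels)
  if (is.character(channels)) channels <- match(channels, tc_task$channels)
  n_win <- length(tc_task$window_end_times)
  n_task <- dim(tc_task$values)[1]
  n_rest <- dim(tc_rest$values)[1]
  n_per <- min(n_task, n_rest)
  k_eff <- min(folds, n_per)
  if (k_eff < folds)
    warning(sprintf("reduced folds to %d (class size %d)", k_eff, n_per))
  acc <- f1 <- numeric(n_win)
  with_seed(seed, {
    for (k in seq_len(n_win)) {
      Xt <- tc_task$values[, channels, k, drop = TRUE]
      Xr <- tc_rest$values[, channels, k, drop = TRUE]
      if (is.null(dim(Xt))) { Xt <- matrix(Xt, ncol = 1); Xr <- matrix(Xr, ncol = 1) }
      res <- matrix(NA_real_, reps, 2)
      for (r in seq_len(reps)) {
        it <- sample(n_task, n_per)
        ir <- sample(n_rest, n_per)
        X <- rbind(Xt[it, , drop = FALSE], Xr[ir, , drop = FALSE])
        y <- rep(c("task", "rest"), each = n_per)
        ok <- stats::complete.cases(X)
        X <- X[ok, , drop = FALSE]; y <- y[ok]
        fold <- stratified_folds(y, k_eff)
        pred <- character(length(y))
        for (fd in seq_len(k_eff)) {
          tr <- fold != fd
          mdl <- lda_train(X[tr, , drop = FALSE], y[tr])
          pred[!tr] <- predict(mdl, X[!tr, , drop = FALSE])
        }
        res[r, ] <- acc_f1(y, pred, "task")
      }
      acc[k] <- mean(res[, 1]); f1[k] <- mean(res[, 2])
    }
  })
  classifier_timecourse(acc, f1, binomial_threshold(n_per, alpha),
                        tc_task$window_end_times)
}

#' Leave-one-participant-out CV classification time courses
#'
#' Each participant contributes a task and a rest [feature_timecourse].
#' For every held-out participant and every window, an LDA is trained on
#' the pooled window-matched features of all remaining participants
#' (rest subsampled to balance) and evaluated on the held-out
#' participant's trials.
#'
#' @param participants List of lists, each with elements `task` and
#'   `rest` ([feature_timecourse]s on a common grid). >= 3 participants.
#' @param channels Feature channels (default all).
#' @param alpha Level for the binomial threshold.
#' @param seed RNG seed (rest subsampling).
#' @return List: `per_participant` (list of `classifier_timecourse`),
#'   `grand_accuracy`, `grand_f1`, `window_end_times`, `threshold`.
#' @export
loso_cv <- function(participants, channels = NULL, alpha = 0.05, seed = 1) {
  if (length(participants) < 3) stop_param("need >= 3 participants")
  grids <- lapply(participants, function(p) p$task$window_end_times)
  n_win <- length(grids[[1]])
  ref <- participants[[1]]$task
  if (is.null(channels)) channels <- seq_along(ref$channels)
  if (is.character(channels)) channels <- match(channels, ref$channels)
  feats <- function(tc, k) tc$values[, channels, k, drop = TRUE]
  out <- vector("list", length(participants))
  with_seed(seed, {
    for (h in seq_along(participants)) {
      held <- participants[[h]]
      n_test <- dim(held$task$values)[1] + dim(held$rest$values)[1]
      acc <- f1 <- numeric(n_win)
      for (k in seq_len(n_win)) {
        Xs <- ys <- list()
        for (o in seq_along(participants)[-h]) {
          p <- participants[[o]]
          Xt <- feats(p$task, k); Xr <- feats(p$rest, k)
          if (is.null(dim(Xt))) { Xt <- matrix(Xt, ncol = 1); Xr <- matrix(Xr, ncol = 1) }
          n_per <- min(nrow(Xt), nrow(Xr))
          Xs <- c(Xs, list(Xt[sample(nrow(Xt), n_per), , drop = FALSE],
                           Xr[sample(nrow(Xr), n_per), , drop = FALSE]))
          ys <- c(ys, list(rep("task", n_per), rep("rest", n_per)))
        }
        X <- do.call(rbind, Xs); y <- unlist(ys)
        ok <- stats::complete.cases(X)
        mdl <- lda_train(X[ok, , drop = FALSE], y[ok])
        Xt <- feats(held$task, k); Xr <- feats(held$rest, k)
        if (is.null(dim(Xt))) { Xt <- matrix(Xt, ncol = 1); Xr <- matrix(Xr, ncol = 1) }
        Xte <- rbind(Xt, Xr)
        yte <- c(rep("task", nrow(Xt)), rep("rest", nrow(Xr)))
        okte <- stats::complete.cases(Xte)
        r <- acc_f1(yte[okte], predict(mdl, Xte[okte, , drop = FALSE]),
                    "task")
        acc[k] <- r[1]; f1[k] <- r[2]
      }
      out[[h]] <- classifier_timecourse(
        acc, f1, binomial_threshold(n_test, alpha),
        held$task$window_end_times)
    }
  })
  accs <- sapply(out, `[[`, "accuracy")
  f1s <- sapply(out, `[[`, "f1")
  list(per_participant = out,
       grand_accuracy = rowMeans(accs), grand_f1 = rowMeans(f1s),
       window_end_times = grids[[1]],
       threshold = mean(sapply(out, `[[`, "threshold")))
}

#' Classifier time-course container
#'
#' @param accuracy Per-window accuracy (%).
#' @param f1 Per-window F1 (task class positive).
#' @param threshold Binomial chance threshold (%).
#' @param window_end_times Window end times (s).
#' @return Object of class `classifier_timecourse` with `peak_accuracy`,
#'   `peak_time` (first window on ties) and `crossing_time` (first window
#'   with accuracy above threshold, or NA) precomputed.
#' @export
classifier_timecourse <- function(accuracy, f1, threshold,
                                  window_end_times) {
  pk <- which.max(accuracy)  # first maximum on ties
  above <- which(accuracy > threshold)
  structure(list(accuracy = accuracy, f1 = f1, threshold = threshold,
                 window_end_times = window_end_times,
                 peak_accuracy = accuracy[pk],
                 peak_time = window_end_times[pk],
                 crossing_time = if (length(above))
                   window_end_times[above[1]] else NA_real_),
            class = "classifier_timecourse")
}

#' @export
print.classifier_timecourse <- function(x, ...) {
  cat(sprintf(
    "classifier_timecourse: peak %.1f%% at %g s (threshold %.1f%%)",
    x$peak_accuracy, x$peak_time, x$threshold))
  if (!is.na(x$crossing_time))
    cat(sprintf(", first crossing %g s", x$crossing_time))
  cat("\n")
  invisible(x)
}

#' Detection times from a classifier time course
#'
#' @param ctc A `classifier_timecourse`.
#' @param event_time Event (movement onset / cue) time in seconds.
#' @return List: `crossing_time` (first window with accuracy above the
#'   threshold), `peak_time` (first argmax), `lead_time` =
#'   `event_time - crossing_time` (positive when the crossing precedes
#'   the event; NA when the threshold is never crossed).
#' @export
detect_times <- function(ctc, event_time = 0) {
  stopifnot(inherits(ctc, "classifier_timecourse"))
  list(crossing_time = ctc$crossing_time,
       peak_time = ctc$peak_time,
       lead_time = if (is.na(ctc$crossing_time)) NA_real_
       else event_time - ctc$crossing_time)
}
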