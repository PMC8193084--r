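# LDA, cross-validation schemes, binomial thresholds, detection times.

mk_feature_tc <- function(n_trials, n_win, mu, sd = 0.05, seed = 1,
                          condition = "task") {
  set.seed(seed)
  v <- array(rnorm(n_trials * 3 * n_win, mu, sd), c(n_trials, 3, n_win))
  feature_timecourse(v, seq_len(n_win) / 10 - 2,
                     rep(condition, n_trials), c("C3", "Cz", "C4"))
}

test_that("lda_train: separation, label symmetry, shrinkage fallback", {
  set.seed(61)
  x0 <- cbind(rnorm(20, 0), rnorm(20), rnorm(20))
  x1 <- cbind(rnorm(20, 5), rnorm(20), rnorm(20))
  X <- rbind(x0, x1); y <- rep(c("a", "b"), each = 20)
  m <- lda_train(X, y)
  expect_equal(predict(m, X), y)         # perfectly separable
  # label swap: same boundary, inverted predictions
  m2 <- lda_train(X, rep(c("b", "a"), each = 20))
  expect_equal(predict(m2, X), rep(c("b", "a"), each = 20))
  # singular covariance (duplicated feature) triggers shrinkage
  Xs <- cbind(X[, 1], X[, 1], X[, 2])
  ms <- lda_train(Xs, y)
  expect_true(ms$shrunk)
  expect_equal(predict(ms, Xs), y)
  expect_error(lda_train(X, rep("a", 40)), "two classes")
})

test_that("binomial threshold: exact value, monotone, degenerate alpha", {
  expect_equal(binomial_threshold(40, 0.05), 65)   # k = 26
  # oracle re-verification by direct tail sums
  expect_lte(1 - stats::pbinom(25, 40, 0.5), 0.05)
  expect_gt(1 - stats::pbinom(24, 40, 0.5), 0.05)
  # monotone decreasing toward 50% + 1.645 * 50 / sqrt(n)
  ns <- c(20, 40, 80, 160, 640)
  th <- vapply(ns, binomial_threshold, numeric(1))
  expect_true(all(diff(th) < 0))
  expect_lt(abs(th[5] - (50 + 1.645 * 50 / sqrt(640))), 1)
  # alpha = 1: one-trial quantum above half
  expect_lte(binomial_threshold(40, 1), 50 + 100 / 40)
  expect_error(binomial_threshold(5), ">= 10")
})

test_that("within-subject CV: null stays near chance, signal detected", {
  n_win <- 12
  rest1 <- mk_feature_tc(40, n_win, 0.6, seed = 71, condition = "rest")
  rest2 <- mk_feature_tc(40, n_win, 0.6, seed = 72, condition = "rest")
  null_ctc <- within_subject_cv(rest1, rest2, folds = 10, reps = 3,
                                seed = 3)
  expect_gte(mean(null_ctc$accuracy >= 40 & null_ctc$accuracy <= 60),
             0.75)
  # separable means: near-perfect accuracy above threshold
  task <- mk_feature_tc(20, n_win, 0.9, sd = 0.03, seed = 73)
  ctc <- within_subject_cv(task, rest1, folds = 5, reps = 3, seed = 3)
  expect_gt(ctc$peak_accuracy, ctc$threshold)
  expect_gt(min(ctc$accuracy), 90)
  # determinism under a fixed seed
  ctc2 <- within_subject_cv(task, rest1, folds = 5, reps = 3, seed = 3)
  expect_identical(ctc$accuracy, ctc2$accuracy)
})

test_that("LOSO CV: identical participants give identical curves", {
  n_win <- 8
  p <- list(task = mk_feature_tc(10, n_win, 0.75, seed = 81),
            rest = mk_feature_tc(10, n_win, 0.60, seed = 82,
                                 condition = "rest"))
  res <- loso_cv(list(p, p, p), seed = 5)
  expect_length(res$per_participant, 3)
  expect_equal(res$per_participant[[1]]$accuracy,
               res$per_participant[[2]]$accuracy)
  expect_gt(mean(res$grand_accuracy), 60)
  expect_error(loso_cv(list(p, p)), ">= 3")
})

test_that("detect_times: crossing, peak tie-break, lead sign", {
  times <- seq(-2, 2, by = 0.5)
  acc <- c(50, 50, 55, 70, 80, 80, 70, 60, 50)
  ctc <- classifier_timecourse(acc, rep(0.5, 9), 65, times)
  dt <- detect_times(ctc, event_time = 0)
  expect_equal(dt$crossing_time, -0.5)     # first window above 65
  expect_equal(dt$peak_time, 0)            # first of the tied maxima
  expect_equal(dt$lead_time, 0.5)          # positive: predicts the event
  expect_lte(ctc$crossing_time, ctc$peak_time)
  # never crosses
  flat <- classifier_timecourse(rep(50, 9), rep(0.5, 9), 65, times)
  expect_true(is.na(detect_times(flat, 0)$crossing_time))
  expect_true(is.na(detect_times(flat, 0)$lead_time))
})

test_that("label permutation at one window centres accuracy at 50%", {
  set.seed(91)
  X <- matrix(rnorm(40 * 3, 0.6, 0.05), 40, 3)
  accs <- vapply(1:30, function(r) {
    y <- sample(rep(c("task", "rest"), each = 20))
    fold <- lrtceeg:::stratified_folds(y, 5)
    pred <- character(40)
    for (fd in 1:5) {
      m <- lda_train(X[fold != fd, ], y[fold != fd])
      pred[fold == fd] <- predict(m, X[fold == fd, , drop = FALSE])
    }
    100 * mean(pred == y)
  }, numeric(1))
  expect_gt(mean(accs), 35); expect_lt(mean(accs), 65)
})
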