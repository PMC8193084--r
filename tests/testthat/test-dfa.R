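# Core DFA machinery.

test_that("integrate_profile matches the hand expansion", {
  p <- integrate_profile(c(1, 2, 3))
  expect_equal(p$y, c(-1, -1, 0))
  expect_equal(integrate_profile(rep(0, 5))$y, rep(0, 5))
  x <- rnorm(1000)
  y <- integrate_profile(x)$y
  expect_lt(abs(y[length(y)]), 1e-9 * max(abs(y)))
  expect_error(integrate_profile(c(1, NA, 3)), "finite")
  expect_error(integrate_profile(1), "short")
})

test_that("box grid: bounds, monotonicity, failure below N = 44", {
  g <- make_box_grid(256)
  expect_equal(g$sizes[1], 10L)
  expect_equal(g$sizes[length(g$sizes)], 64L)
  expect_true(all(diff(g$sizes) > 0))
  expect_true(all(g$sizes >= 10 & g$sizes <= 64))
  expect_error(make_box_grid(43), "too short")
  # approximately log2-equidistant: max gap ratio bounded
  lg <- diff(log2(g$sizes))
  expect_lt(max(lg) / min(lg), 4)
})

test_that("fluctuation: exact zeros on lines, fwd = bwd when divisible", {
  # an exactly linear profile is removed by the per-box linear detrending
  prof <- structure(list(y = 2 * (1:256) + 3, N = 256L, x_mean = 0),
                    class = "integrated_profile")
  fl <- fluctuation(prof, make_box_grid(256))
  expect_true(all(fl$F < 1e-10))
  # N divisible by n: forward and backward partitions coincide, so the
  # averaged F equals the single-direction RMS
  x <- gen_fgn(256, 0.7, 1)
  y <- cumsum(x - mean(x))
  g <- structure(list(sizes = c(16L, 32L, 64L)), class = "box_grid")
  fl2 <- fluctuation(integrate_profile(x), g)
  for (i in 1:3)
    expect_equal(fl2$F[i],
                 lrtceeg:::box_detrended_rms(y, g$sizes[i]),
                 tolerance = 1e-14)
})

test_that("fluctuation matches the naive loop oracle to 1e-10 relative", {
  set.seed(42)
  for (rep in 1:5) {
    N <- sample(64:512, 1)
    x <- rnorm(N)
    g <- make_box_grid(N, k_sizes = 10)
    fast <- fluctuation(x, g)$F
    slow <- naive_fluctuation(x, g$sizes)
    expect_equal(fast, slow, tolerance = 1e-10)
  }
})

test_that("dfa_exponent: white-noise slope, scale equivariance, errors", {
  set.seed(7)
  h <- mean(vapply(1:20, function(i) dfa_exponent(rnorm(4096))$H,
                   numeric(1)))
  expect_gt(h, 0.45); expect_lt(h, 0.55)
  # scale equivariance: slope exact, intercept shifts by log2|c|
  x <- gen_fgn(512, 0.7, 3)
  r1 <- dfa_exponent(x)
  r2 <- dfa_exponent(5 * x)
  expect_equal(r1$H, r2$H, tolerance = 1e-12)
  expect_equal(r2$intercept - r1$intercept, log2(5), tolerance = 1e-9)
  expect_error(dfa_exponent(rep(1, 256)), "degenerate")
})

test_that("shuffling destroys memory: H near 0.5", {
  set.seed(11)
  h <- vapply(1:100, function(s) {
    x <- sample(gen_fgn(256, 0.8, s %% 20 + 1))
    dfa_exponent(x * hann256, grid256)$H
  }, numeric(1))
  expect_gt(mean(h), 0.45); expect_lt(mean(h), 0.55)
})

test_that("h_timecourse: shape, smoothing identity, grid rule", {
  ts <- small_trialset(3, 768)
  ws <- sliding_windows(ts, 2, 0.1)
  tc1 <- h_timecourse(ws, alpha_smooth = 1)
  tc2 <- h_timecourse(ws, alpha_smooth = 0.3)
  expect_equal(dim(tc1$values), c(3, 3, 41))
  # alpha_smooth = 1 equals unsmoothed; 0.3 differs
  raw <- dfa_exponent(ws$windows[1, 1, 1, ], grid256)$H
  expect_equal(tc1$values[1, 1, 1], raw)
  expect_false(isTRUE(all.equal(tc1$values[1, 1, 41],
                                tc2$values[1, 1, 41])))
  # the 2 s / 128 Hz window uses the [10, 64]-sample grid: 78 ms - 0.5 s,
  # inside [max(k+2, Fs/Fmax), min(N/4, Fs/Fmin)] for 0.5-45 Hz
  g <- make_box_grid(256)
  expect_gte(g$sizes[1], max(1 + 2, 128 / 45))
  expect_lte(g$sizes[length(g$sizes)], min(256 / 4, 128 / 0.5))
})

test_that("stitched DFA: grid brackets and envelope exponent recovery", {
  ts <- small_trialset(40, 768, H = 0.6)
  ws <- sliding_windows(ts, 2, 0.1, taper = "none")
  seg <- stitch(ws, ws$window_end_times[5], 1)
  r <- stitched_dfa(seg, c(2, 20))
  # 80 s segment: box sizes within [2^8, 2^11]
  expect_gte(min(r$fluctuations$n), 256)
  expect_lte(max(r$fluctuations$n), 2048)
  b <- lrtceeg:::stitched_box_bounds(128, c(2, 8))
  expect_equal(b, c(256, 1024))  # the 44 s bracket [2^8, 2^10]
  expect_error(stitched_dfa(stitched_segment(rnorm(1000), 128, 0, 2),
                            c(2, 20)), "exceeds")
})
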