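# Preprocessing: filtering, resampling, windowing, envelope, stitching,
# smoothing.

test_that("bandpass: passthrough, stopband, zero phase", {
  fs <- 128
  t <- (0:2047) / fs
  y <- bandpass(sin(2 * pi * 10 * t), 0.5, 45, fs)
  expect_gt(max(abs(y[500:1500])), 0.95)
  expect_lt(max(abs(y[500:1500])), 1.05)
  y60 <- bandpass(sin(2 * pi * 60 * t), 0.5, 45, fs)
  expect_lt(20 * log10(max(abs(y60[500:1500]))), -20)
  # zero-phase: Gaussian bump peak preserved to within one sample
  g <- exp(-((t - 8)^2) / (2 * 0.05^2))
  expect_lte(abs(which.max(bandpass(g, 0.5, 45, fs)) - which.max(g)), 1)
  expect_error(bandpass(rnorm(100), 45, 0.5, fs), "low < high")
  expect_error(bandpass(rnorm(100), 0.5, 70, fs), "fs/2")
})

test_that("zero-phase property: cross-correlation lag is 0", {
  fs <- 128
  x <- gen_fgn(2048, 0.7, 11)
  y <- bandpass(x, 0.5, 45, fs)
  cc <- stats::ccf(x, y, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("downsample: lengths and tone survival", {
  expect_length(downsample(sin(2 * pi * 10 * (0:6143) / 1024),
                           1024, 128), 768)
  r <- downsample(sin(2 * pi * 10 * (0:1119) / 160), 160, 128)
  expect_length(r, 896)  # 5:4 resampling
  expect_gt(max(abs(r[200:600])), 0.9)
  expect_lt(max(abs(r[200:600])), 1.1)
  expect_error(downsample(rnorm(10), 128, 256), "exceed")
})

test_that("sliding windows: counts, causal end times, taper", {
  ts6 <- small_trialset(2, 768)       # 6 s at 128 Hz
  ws <- sliding_windows(ts6, 2, 0.1)
  expect_equal(dim(ws$windows)[3], 41)
  expect_equal(dim(ws$windows)[4], 256)
  ts7 <- small_trialset(2, 896)       # 7 s
  expect_equal(dim(sliding_windows(ts7, 2, 0.1)$windows)[3], 51)
  # consecutive end times differ by the step, up to the one-sample
  # quantization forced by the non-integer 12.8-sample step at 128 Hz
  expect_true(all(abs(diff(ws$window_end_times) - 0.1) <= 1 / 128))
  expect_equal(ws$window_end_times[41] - ws$window_end_times[1], 4,
               tolerance = 1e-9)
  # untapered windows of a constant series stay constant
  tsc <- small_trialset(2, 768)
  tsc$data[] <- 3
  wsc <- sliding_windows(tsc, 2, 0.1, taper = "none")
  expect_true(all(wsc$windows == 3))
  # tapered windows match constant * hanning
  wst <- sliding_windows(tsc, 2, 0.1, taper = "hanning")
  expect_equal(wst$windows[1, 1, 5, ], 3 * hann256, tolerance = 1e-12)
  expect_error(sliding_windows(small_trialset(2, 128), 2, 0.1), "longer")
})

test_that("alpha envelope: identity, demodulation, non-negativity", {
  fs <- 128
  n <- 1024
  t <- (0:(n - 1)) / fs
  a <- array(NA_real_, c(2, 3, n))
  modu <- 1 + 0.5 * sin(2 * pi * 0.5 * t)
  for (i in 1:2) for (j in 1:3)
    a[i, j, ] <- if (j == 1) 2 * sin(2 * pi * 10 * t)
  else sin(2 * pi * 10 * t) * modu
  ts <- trial_set(a, fs, 512, rep("rest", 2), c("C3", "Cz", "C4"))
  env <- alpha_envelope(ts)
  expect_true(all(env$data >= 0))
  interior <- 100:900
  expect_lt(max(abs(env$data[1, 1, interior] - 2) / 2), 0.05)
  expect_gt(stats::cor(env$data[1, 2, interior], modu[interior]), 0.95)
})

test_that("stitch: lengths, order, round trip, grid errors", {
  ts <- small_trialset(40, 768)
  ws <- sliding_windows(ts, 2, 0.1, taper = "none")
  t0 <- ws$window_end_times[10]
  seg <- stitch(ws, t0, "C3")
  expect_length(seg$series, 10240)           # 80 s at 128 Hz
  expect_equal(length(seg$series) / seg$fs, 80)
  seg22 <- stitch(sliding_windows(small_trialset(22, 768), 2, 0.1,
                                  taper = "none"), t0, 1)
  expect_length(seg22$series, 5632)          # 44 s
  # round trip: slicing recovers the source windows bit-exactly
  m <- matrix(seg$series, nrow = 256)
  for (i in c(1, 17, 40))
    expect_identical(m[, i], ws$windows[i, 1, 10, ])
  expect_error(stitch(ws, 0.031, 1), "not on the grid")
  expect_error(stitch(ws, t0, "Pz"), "channel")
  # identical trials -> repeated window
  ts2 <- small_trialset(2, 768)
  ts2$data[2, , ] <- ts2$data[1, , ]
  ws2 <- sliding_windows(ts2, 2, 0.1, taper = "none")
  s2 <- stitch(ws2, t0, 1)$series
  expect_identical(s2[1:256], s2[257:512])
})

test_that("exp_smooth closed forms", {
  v <- rnorm(20)
  expect_identical(exp_smooth(v, 1), v)
  expect_equal(exp_smooth(rep(4, 10), 0.3), rep(4, 10))
  step <- c(0, 1, 1, 1)
  expect_equal(exp_smooth(step, 0.5), c(0, 0.5, 0.75, 0.875))
  expect_error(exp_smooth(v, 0), "outside")
  expect_error(exp_smooth(v, 1.5), "outside")
})
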