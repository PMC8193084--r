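# Synthetic generators: fGn, ARFIMA, alpha component, trials, datasets.

test_that("gen_fgn is deterministic, validated, and white at H = 0.5", {
  expect_identical(gen_fgn(512, 0.8, 7), gen_fgn(512, 0.8, 7))
  expect_false(identical(gen_fgn(512, 0.8, 7), gen_fgn(512, 0.8, 8)))
  expect_error(gen_fgn(4096, 1.2, 1), "outside")
  expect_error(gen_fgn(1, 0.5, 1), "n_samples")
  x <- gen_fgn(4096, 0.5, 3)
  r1 <- stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(r1), 0.05)
  # zero mean, unit variance in expectation
  expect_lt(abs(mean(x)), 0.1)
  expect_lt(abs(stats::sd(x) - 1), 0.1)
})

test_that("gen_fgn H = 0.8 windows recover H via DFA", {
  h <- vapply(1:100, function(s)
    dfa_exponent(gen_fgn(4096, 0.8, s))$H, numeric(1))
  expect_gt(mean(h), 0.75)
  expect_lt(mean(h), 0.85)
})

test_that("gen_arfima reduces correctly and carries long memory", {
  # d = 0, no ARMA part: white Gaussian noise
  x <- gen_arfima(2048, d = 0, seed = 1)
  expect_identical(x, with(list(), { set.seed(1L); stats::rnorm(2048) }))
  expect_gt(dfa_exponent(x)$H, 0.4)
  expect_lt(dfa_exponent(x)$H, 0.6)
  # d = 0 equals the pure ARMA path given the same innovations
  eps <- stats::rnorm(512)
  expect_identical(gen_arfima(512, ar = 0.5, d = 0, innovations = eps),
                   gen_arfima(512, ar = 0.5, d = 0, innovations = eps))
  ar_direct <- as.numeric(stats::filter(eps, 0.5, method = "recursive"))
  expect_equal(gen_arfima(512, ar = 0.5, d = 0, innovations = eps),
               ar_direct)
  # d = 0.3 fractional noise: H ~= d + 0.5
  h <- vapply(1:100, function(s)
    dfa_exponent(gen_arfima(256, d = 0.3, seed = s) * hann256,
                 grid256)$H, numeric(1))
  expect_gt(mean(h), 0.75)
  expect_lt(mean(h), 0.85)
  expect_error(gen_arfima(100, ar = 1.2, d = 0), "stationary")
  expect_error(gen_arfima(100, d = 0.7), "outside")
})

test_that("alpha component: AM identity, carrier peak, envelope recovery", {
  fs <- 128
  # degenerate envelope path: constant envelope
  x <- gen_alpha_component(1024, fs, 0.8, seed = 1, env_sd = 0)
  env <- hilbert_envelope(x)
  interior <- 100:900
  expect_lt(max(abs(env[interior] - 1)), 0.05)
  # spectral peak within 8-13 Hz
  x2 <- gen_alpha_component(4096, fs, 0.8, seed = 2)
  sp <- Mod(stats::fft(x2))[1:2048]
  fpeak <- (which.max(sp) - 1) * fs / 4096
  expect_gt(fpeak, 8); expect_lt(fpeak, 13)
  expect_error(gen_alpha_component(512, fs, 0.3), "outside")
  # envelope Hurst recovery on 44 s at 2-8 s timescales
  n <- 44 * fs
  h <- vapply(1:20, function(s) {
    x <- gen_alpha_component(n, fs, 0.8, seed = s)
    b <- bandpass(x, 8, 13, fs)
    seg <- stitched_segment(hilbert_envelope(b), fs, 0, 22)
    stitched_dfa(seg, c(2, 8))$H
  }, numeric(1))
  expect_gt(mean(h), 0.7)
  expect_lt(mean(h), 0.9)
})

test_that("DFA recovery is monotone in generator H", {
  hs <- vapply(c(0.55, 0.65, 0.75, 0.85), function(H)
    mean(vapply(1:50, function(s)
      dfa_exponent(gen_fgn(256, H, 7000 + s) * hann256, grid256)$H,
      numeric(1))), numeric(1))
  expect_true(all(diff(hs) > 0))
})

test_that("gen_trial produces the stated shapes and ground truth", {
  spec <- synthetic_spec(n_trials_per_condition = 2)
  tr <- gen_trial(spec, "task", seed = 5)
  expect_equal(dim(tr$data), c(3, 768))  # 6 s x 128 Hz
  expect_equal(rownames(tr$data), c("C3", "Cz", "C4"))
  expect_identical(tr$truth$onset_s, 0)  # onset_jitter = 0 -> exactly 0
  expect_true(all(tr$truth$H_profile >= spec$H_rest - 1e-12 &
                    tr$truth$H_profile <= spec$H_move + 1e-12))
  # rest trial: flat truth profile
  tr_r <- gen_trial(spec, "rest", seed = 5)
  expect_true(all(tr_r$truth$H_profile == spec$H_rest))
  # jittered onset stays within bounds
  spec_j <- synthetic_spec(onset_jitter = 1)
  on <- vapply(1:20, function(s)
    gen_trial(spec_j, "task", seed = s)$truth$onset_s, numeric(1))
  expect_true(all(abs(on) <= 0.5))
  expect_gt(stats::sd(on), 0)
})

test_that("gen_dataset: sizes, labels, reproducibility", {
  spec <- synthetic_spec(n_trials_per_condition = 3)
  ds <- gen_dataset(spec)
  expect_s3_class(ds$trials, "trial_set")
  expect_equal(dim(ds$trials$data), c(6, 3, 768))
  expect_equal(ds$trials$condition, rep(c("task", "rest"), each = 3))
  ds2 <- gen_dataset(spec)
  expect_identical(ds$trials$data, ds2$trials$data)
  spec7 <- synthetic_spec(n_trials_per_condition = 2,
                          paradigm = "cued_continuous")
  expect_equal(dim(gen_dataset(spec7)$trials$data)[3], 896)  # 7 s trials
  # truth profiles reproducible from (spec, seed)
  expect_identical(ds$truth, gen_dataset(spec)$truth)
})
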