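# Shared fixtures, built in code.

hann256 <- lrtceeg:::hanning(256)
grid256 <- make_box_grid(256)

# collection of tapered fGn windows with a common H
fgn_windows <- function(n_windows, H, n = 256, seed0 = 0, taper = TRUE) {
  lapply(seq_len(n_windows), function(s) {
    x <- gen_fgn(n, H, seed0 + s)
    if (taper) x * lrtceeg:::hanning(n) else x
  })
}

# small trial_set: pure fGn, 3 channels
small_trialset <- function(n_trials = 4, n_samp = 768, fs = 128, H = 0.6,
                           seed0 = 100, condition = rep("rest", n_trials)) {
  a <- array(NA_real_, c(n_trials, 3, n_samp))
  for (i in seq_len(n_trials)) for (j in 1:3)
    a[i, j, ] <- gen_fgn(n_samp, H, seed0 + 10 * i + j)
  trial_set(a, fs, time0_index = n_samp / 2, condition,
            c("C3", "Cz", "C4"))
}

# naive, loop-based DFA fluctuation oracle (independent of the package
# implementation): forward and backward box partitions, per-box linear
# least squares from scalar normal-equation sums, RMS over covered
# samples. Deliberately scalar loops, no shared code with the package.
naive_fluctuation <- function(x, sizes) {
  y <- cumsum(x - mean(x))
  N <- length(y)
  out <- numeric(length(sizes))
  for (si in seq_along(sizes)) {
    n <- sizes[si]
    nb <- floor(N / n)
    rms_dir <- function(offset) {
      sq <- 0
      for (b in seq_len(nb)) {
        st <- stt <- sy <- sty <- 0
        for (k in seq_len(n)) {
          yi <- y[offset + (b - 1) * n + k]
          st <- st + k; stt <- stt + k * k
          sy <- sy + yi; sty <- sty + k * yi
        }
        slope <- (n * sty - st * sy) / (n * stt - st * st)
        icpt <- (sy - slope * st) / n
        for (k in seq_len(n)) {
          r <- y[offset + (b - 1) * n + k] - (icpt + slope * k)
          sq <- sq + r * r
        }
      }
      sqrt(sq / (nb * n))
    }
    out[si] <- (rms_dir(0) + rms_dir(N - nb * n)) / 2
  }
  out
}
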