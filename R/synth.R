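# Synthetic EEG-like generators with known ground-truth Hurst dynamics.
#
# Broadband "arrhythmic" activity is modelled as fractional Gaussian noise
# (fGn) with Hurst exponent H in [0.5, 1); an oscillatory alpha component is
# a 10 Hz carrier with a slowly varying positive envelope whose fluctuations
# themselves carry a prescribed Hurst exponent. Task trials cross-fade
# between stationary segments of different H so every downstream estimator
# can be checked against recorded ground truth.

#' Exact fractional Gaussian noise by circulant embedding
#'
#' Davies–Harte construction: the autocovariance of fGn,
#' \eqn{\gamma(k) = (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})/2}, is embedded in
#' a circulant matrix whose eigenvalues (computed by FFT) are provably
#' non-negative for fGn, so the synthesis is exact in distribution: zero
#' mean, unit variance, the exact fGn covariance at every lag.
#'
#' @param n_samples Series length (>= 2).
#' @param H Hurst exponent, in (0, 1). H = 0.5 gives white noise; H in
#'   (0.5, 1) gives persistent long memory.
#' @param seed Integer seed; the same `(n_samples, H, seed)` always returns
#'   the identical series. `NULL` uses the current RNG stream.
#' @return Numeric vector of length `n_samples`.
#' @examples
#' x <- gen_fgn(1024, H = 0.8, seed = 1)
#' @export
gen_fgn <- function(n_samples, H, seed = NULL) {
  if (!is.numeric(n_samples) || n_samples < 2)
    stop_param("`n_samples` must be >= 2")
  assert_scalar_in(H, "H", 0, 1, lower_open = TRUE, upper_open = TRUE)
  n <- as.integer(n_samples)
  m <- stats::nextn(2L * (n - 1L), 2L)  # circulant size, power of 2 >= 2(n-1)
  k <- 0:(m / 2)
  g <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  crow <- c(g, rev(g[2:(m / 2)]))      # symmetric first row of the embedding
  lam <- Re(stats::fft(crow))
  # fGn embeddings are non-negative definite; clip tiny negative round-off
  lam[lam < 0 & lam > -1e-8 * max(lam)] <- 0
  if (any(lam < 0))
    stop_param("circulant embedding produced negative eigenvalues (H = %g)", H)
  with_seed(seed, {
    z <- stats::rnorm(m) + 1i * stats::rnorm(m)
    # enforce Hermitian symmetry so the synthesis is real
    z[1] <- Re(z[1]) * sqrt(2)
    z[m / 2 + 1] <- Re(z[m / 2 + 1]) * sqrt(2)
    z[(m / 2 + 2):m] <- Conj(z[rev(2:(m / 2))])
    w <- stats::fft(sqrt(lam / (2 * m)) * z)
    Re(w[seq_len(n)])
  })
}

#' Binomial fractional-differencing weights
#'
#' Expansion of \eqn{(1-B)^d}: \eqn{w_0 = 1}, \eqn{w_j = w_{j-1}(j-1-d)/j}.
#' Negative `d` gives the fractional-integration weights of \eqn{(1-B)^{-|d|}}.
#'
#' @param d Fractional order.
#' @param n Number of weights.
#' @return Numeric vector of length `n`.
#' @export
frac_diff_weights <- function(d, n) {
  w <- numeric(n)
  w[1] <- 1
  if (n > 1) for (j in seq_len(n - 1L)) w[j + 1] <- w[j] * (j - 1 - d) / j
  w
}

#' Simulate an ARFIMA(p, d, q) series
#'
#' Gaussian innovations are passed through the ARMA(p, q) filter and then
#' fractionally integrated by applying \eqn{(1-B)^{-d}} with binomial weights
#' truncated at the series length. For pure fractional noise (`ar = ma =
#' numeric(0)`), the DFA exponent of the output is approximately `d + 0.5`.
#'
#' @param n_samples Series length.
#' @param ar,ma AR and MA coefficient vectors (may be empty).
#' @param d Fractional order, |d| < 0.5.
#' @param seed Integer seed (see [gen_fgn]).
#' @param innovations Optional explicit innovation series (length
#'   `n_samples`); overrides `seed`. Used to check that `d = 0` reduces to
#'   the plain ARMA path.
#' @return Numeric vector of length `n_samples`.
#' @export
gen_arfima <- function(n_samples, ar = numeric(0), d = 0, ma = numeric(0),
                       seed = NULL, innovations = NULL) {
  if (!is.numeric(n_samples) || n_samples < 2)
    stop_param("`n_samples` must be >= 2")
  assert_scalar_in(d, "d", -0.5, 0.5, lower_open = TRUE, upper_open = TRUE)
  if (length(ar) && any(Mod(polyroot(c(1, -ar))) <= 1))
    stop_param("AR polynomial is not stationary")
  if (length(ma) && any(Mod(polyroot(c(1, ma))) < 1))
    stop_param("MA polynomial is not invertible")
  n <- as.integer(n_samples)
  eps <- if (!is.null(innovations)) {
    stopifnot(length(innovations) == n)
    as.numeric(innovations)
  } else with_seed(seed, stats::rnorm(n))
  x <- eps
  if (length(ma)) {
    x <- as.numeric(stats::filter(x, c(1, ma), method = "convolution",
                                  sides = 1))
    x[seq_along(ma)] <- eps[seq_along(ma)]  # warm-up: pass innovations through
  }
  if (length(ar))
    x <- as.numeric(stats::filter(x, ar, method = "recursive"))
  if (d != 0)
    x <- conv_causal(x, frac_diff_weights(-d, n))
  x
}

#' Synthetic 10 Hz alpha component with long-memory amplitude envelope
#'
#' A sinusoidal carrier at `f_carrier` is amplitude-modulated by a strictly
#' positive, slowly varying envelope. The envelope is built from fGn with
#' Hurst exponent `envelope_H`, low-pass smoothed (moving average over
#' `smooth_s` seconds, which only touches timescales well below those
#' analysed) and mapped through a softplus so it stays positive while
#' remaining approximately affine in the fGn — preserving the envelope's
#' scaling exponent on the 2–20 s timescales where envelope LRTC is read out.
#'
#' @param n_samples Series length.
#' @param fs Sampling rate (Hz).
#' @param envelope_H Hurst exponent of the envelope fluctuations, in
#'   \[0.5, 1).
#' @param seed Integer seed.
#' @param f_carrier Carrier frequency (Hz), default 10 within the 8–13 Hz
#'   alpha band.
#' @param env_sd Relative fluctuation size of the envelope driver (kept
#'   small so the softplus operates in its quasi-linear range); `env_sd = 0`
#'   gives a constant envelope.
#' @param smooth_s Moving-average smoothing length in seconds.
#' @param envelope Logical; return the envelope instead of the modulated
#'   carrier (used to expose ground truth).
#' @return Numeric vector of length `n_samples`.
#' @export
gen_alpha_component <- function(n_samples, fs, envelope_H, seed = NULL,
                                f_carrier = 10, env_sd = 0.35,
                                smooth_s = 0.25, envelope = FALSE) {
  assert_scalar_in(envelope_H, "envelope_H", 0.5, 1, upper_open = TRUE)
  n <- as.integer(n_samples)
  env <- alpha_envelope_driver(n, fs, envelope_H, seed, env_sd, smooth_s)
  if (envelope) return(env)
  t <- (seq_len(n) - 1) / fs
  env * cos(2 * pi * f_carrier * t)
}

# Strictly positive slow envelope with Hurst exponent envelope_H.
alpha_envelope_driver <- function(n, fs, envelope_H, seed, env_sd, smooth_s) {
  if (env_sd == 0) return(rep(1, n))
  z <- gen_fgn(n, envelope_H, seed)
  k <- max(1L, as.integer(round(smooth_s * fs)))
  if (k > 1L) {
    kern <- rep(1 / k, k)
    z <- as.numeric(stats::filter(c(rev(z[seq_len(k)]), z), kern,
                                  sides = 1))[-seq_len(k)]
  }
  z <- z / stats::sd(z)
  # softplus around 1: positive, ~affine for small env_sd * z
  log1p(exp(2 * (1 + env_sd * z))) / 2
}

#' Specification of a synthetic EEG dataset
#'
#' Collects every generator parameter with defaults mirroring the
#' experimental paradigms the package targets: self-initiated single taps
#' (6 s trials, −3..+3 s around onset) or cued continuous tasks (7 s trials,
#' −3..+4 s around the cue).
#'
#' @param fs Sampling rate in Hz.
#' @param n_trials_per_condition Trials generated per condition.
#' @param paradigm `"asynchronous_tap"` or `"cued_continuous"`.
#' @param t_pre,t_post Trial bounds in seconds relative to the event
#'   (onset or cue); `t_pre < 0 < t_post`.
#' @param H_rest,H_move Baseline and task-period broadband Hurst exponents,
#'   both in \[0.5, 1).
#' @param H_env_rest,H_env_move Hurst exponents of the alpha amplitude
#'   envelope at rest and during the task.
#' @param alpha_amp Relative amplitude of the 10 Hz component (broadband
#'   fGn has unit variance).
#' @param task_start Start of the H modulation in seconds relative to the
#'   event; negative values model pre-onset movement intention.
#' @param task_duration Length of the task-locked modulation plateau (s).
#' @param ramp Cross-fade ramp length (s) at each edge of the task interval.
#' @param onset_jitter For the asynchronous paradigm, the true onset is
#'   drawn uniformly from ±`onset_jitter`/2 around 0 s.
#' @param noise_sd Additive white measurement-noise SD.
#' @param seed Master RNG seed; all per-trial sub-seeds derive from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(fs = 128,
                           n_trials_per_condition = 40,
                           paradigm = c("asynchronous_tap", "cued_continuous"),
                           t_pre = NULL, t_post = NULL,
                           H_rest = 0.60, H_move = 0.75,
                           H_env_rest = 0.80, H_env_move = 0.65,
                           alpha_amp = 0.5,
                           task_start = NULL, task_duration = NULL,
                           ramp = 0.5,
                           onset_jitter = 0,
                           noise_sd = 0.1,
                           seed = 1L) {
  paradigm <- match.arg(paradigm)
  if (is.null(t_pre))  t_pre  <- -3
  if (is.null(t_post)) t_post <- if (paradigm == "asynchronous_tap") 3 else 4
  if (is.null(task_start))
    task_start <- if (paradigm == "asynchronous_tap") -0.5 else 0
  if (is.null(task_duration))
    task_duration <- if (paradigm == "asynchronous_tap") 2 else 4
  if (!(fs > 90)) stop_param("`fs` must exceed 90 Hz (2 x 45 Hz band edge)")
  if (!(t_pre < 0 && t_post > 0)) stop_param("need t_pre < 0 < t_post")
  if (task_duration <= 0) stop_param("`task_duration` must be positive")
  for (nm in c("H_rest", "H_move", "H_env_rest", "H_env_move"))
    assert_scalar_in(get(nm), nm, 0.5, 1, upper_open = TRUE)
  structure(list(
    fs = fs, n_trials_per_condition = as.integer(n_trials_per_condition),
    paradigm = paradigm, t_pre = t_pre, t_post = t_post,
    H_rest = H_rest, H_move = H_move,
    H_env_rest = H_env_rest, H_env_move = H_env_move,
    alpha_amp = alpha_amp, task_start = task_start,
    task_duration = task_duration, ramp = ramp,
    onset_jitter = onset_jitter, noise_sd = noise_sd,
    seed = as.integer(seed)), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic EEG spec:", x$paradigm, "\n")
  cat(sprintf("  %d trials/condition, fs = %g Hz, trial %g..%g s\n",
              x$n_trials_per_condition, x$fs, x$t_pre, x$t_post))
  cat(sprintf("  H_BB %g -> %g, H_env %g -> %g over task [%g, %g] s\n",
              x$H_rest, x$H_move, x$H_env_rest, x$H_env_move,
              x$task_start, x$task_start + x$task_duration))
  invisible(x)
}

# Cross-fade weight profile: 0 outside the task interval, 1 on the plateau,
# raised-cosine ramps of length `ramp` seconds at both edges.
task_weight_profile <- function(t, task_start, task_duration, ramp) {
  up_end <- task_start
  dn_beg <- task_start + task_duration
  w <- numeric(length(t))
  w[t >= up_end & t <= dn_beg] <- 1
  if (ramp > 0) {
    i <- t > up_end - ramp & t < up_end
    w[i] <- 0.5 * (1 - cos(pi * (t[i] - (up_end - ramp)) / ramp))
    i <- t > dn_beg & t < dn_beg + ramp
    w[i] <- 0.5 * (1 + cos(pi * (t[i] - dn_beg) / ramp))
  }
  w
}

#' Generate one synthetic trial with ground truth
#'
#' A 3-channel (C3, Cz, C4) trial. Each channel is the sum of (i) broadband
#' fGn whose local Hurst exponent ramps from `H_rest` to `H_move` over the
#' task interval and back (realized by cross-fading two independent
#' stationary fGn series with raised-cosine ramps), (ii) a 10 Hz alpha
#' component whose envelope Hurst exponent drops from `H_env_rest` to
#' `H_env_move` during the task, and (iii) white measurement noise.
#' Channels are generated i.i.d.; the Hurst *profiles* are common.
#'
#' @param spec A [synthetic_spec()].
#' @param condition `"task"` or `"rest"`.
#' @param seed Integer seed for this trial.
#' @return List with `data` (channels x samples matrix, rownames C3/Cz/C4),
#'   `truth` (list: `onset_s`, per-sample `H_profile` and `H_env_profile`,
#'   time axis `t`), and `fs`.
#' @export
gen_trial <- function(spec, condition = c("task", "rest"), seed = NULL) {
  condition <- match.arg(condition)
  stopifnot(inherits(spec, "synthetic_spec"))
  fs <- spec$fs
  n <- as.integer(round((spec$t_post - spec$t_pre) * fs))
  t <- spec$t_pre + (seq_len(n) - 1) / fs
  channels <- c("C3", "Cz", "C4")

  onset <- 0
  if (condition == "task" && spec$paradigm == "asynchronous_tap" &&
      spec$onset_jitter > 0) {
    onset <- with_seed(derive_seed(seed, 900L),
                       stats::runif(1, -spec$onset_jitter / 2,
                                    spec$onset_jitter / 2))
  }
  w <- if (condition == "task")
    task_weight_profile(t, onset + spec$task_start, spec$task_duration,
                        spec$ramp) else numeric(n)

  data <- matrix(0, nrow = 3, ncol = n, dimnames = list(channels, NULL))
  for (ch in seq_len(3L)) {
    s0 <- derive_seed(seed, ch)
    bb_rest <- gen_fgn(n, spec$H_rest, derive_seed(s0, 1L))
    bb <- if (condition == "task") {
      bb_move <- gen_fgn(n, spec$H_move, derive_seed(s0, 2L))
      norm <- sqrt((1 - w)^2 + w^2)        # keep variance ~constant in fades
      ((1 - w) * bb_rest + w * bb_move) / norm
    } else bb_rest
    env_rest <- alpha_envelope_driver(n, fs, spec$H_env_rest,
                                      derive_seed(s0, 3L), 0.35, 0.25)
    env <- if (condition == "task") {
      env_move <- alpha_envelope_driver(n, fs, spec$H_env_move,
                                        derive_seed(s0, 4L), 0.35, 0.25)
      (1 - w) * env_rest + w * env_move
    } else env_rest
    carrier <- cos(2 * pi * 10 * (seq_len(n) - 1) / fs)
    noise <- with_seed(derive_seed(s0, 5L), stats::rnorm(n, sd = spec$noise_sd))
    data[ch, ] <- bb + spec$alpha_amp * env * carrier + noise
  }

  H_profile <- spec$H_rest + w * (spec$H_move - spec$H_rest)
  H_env_profile <- spec$H_env_rest + w * (spec$H_env_move - spec$H_env_rest)
  list(data = data,
       truth = list(onset_s = onset, t = t,
                    H_profile = H_profile, H_env_profile = H_env_profile),
       fs = fs)
}

#' Generate a labelled synthetic dataset
#'
#' `n_trials_per_condition` trials for each requested condition, assembled
#' into a [trial_set] plus a ground-truth record. Fully reproducible from
#' `spec$seed`; per-trial sub-seeds are derived deterministically.
#'
#' @param spec A [synthetic_spec()].
#' @param conditions Character vector of conditions to generate.
#' @return List with `trials` (a `trial_set`) and `truth` (per-trial list).
#' @export
gen_dataset <- function(spec, conditions = c("task", "rest")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_per <- spec$n_trials_per_condition
  n_samp <- as.integer(round((spec$t_post - spec$t_pre) * spec$fs))
  n_tot <- n_per * length(conditions)
  data <- array(NA_real_, dim = c(n_tot, 3L, n_samp))
  labels <- character(n_tot)
  truth <- vector("list", n_tot)
  i <- 0L
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    for (k in seq_len(n_per)) {
      i <- i + 1L
      # sub-seed by condition *position*, so repeated condition names
      # (e.g. two independent rest sets) never share a stream
      tr <- gen_trial(spec, cond,
                      seed = derive_seed(spec$seed, 1000L * ci + k))
      data[i, , ] <- tr$data
      labels[i] <- cond
      truth[[i]] <- tr$truth
    }
  }
  ts <- trial_set(data, fs = spec$fs,
                  time0_index = as.integer(round(-spec$t_pre * spec$fs)) + 1L,
                  condition = labels, channels = c("C3", "Cz", "C4"))
  list(trials = ts, truth = truth, spec = spec)
}
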