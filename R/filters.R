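# Digital filtering primitives: Butterworth design (bilinear transform),
# zero-phase forward-backward application, polyphase rational resampling
# with a Kaiser-windowed anti-alias FIR, and the FFT Hilbert transform.
# Implemented here because no signal-processing package is available in the
# supported dependency set.

# Analog Butterworth prototype poles for order n (cutoff 1 rad/s).
butter_proto_poles <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

# Bilinear transform of analog zeros/poles/gain to digital at rate fs = 2
# (prewarped design frequencies are in rad/s).
bilinear_zpk <- function(z, p, k, fs = 2) {
  fs2 <- 2 * fs
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  kd <- k * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- c(zd, rep(-1 + 0i, length(p) - length(z)))  # zeros at Nyquist
  list(z = zd, p = pd, k = kd)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Design a digital Butterworth filter
#'
#' Bilinear-transform design with frequency prewarping. For
#' `type = "pass"`, `w` is `c(low, high)` as fractions of the Nyquist
#' frequency; for `"low"`/`"high"` a single edge.
#'
#' @param order Filter order (the bandpass transfer function has `2*order`
#'   poles, as is conventional for "an order-n bandpass Butterworth").
#' @param w Normalized edge frequency/frequencies in (0, 1), units of
#'   Nyquist.
#' @param type `"low"`, `"high"` or `"pass"`.
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_design <- function(order, w, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  if (any(w <= 0) || any(w >= 1)) stop_param("edges must lie in (0, 1)")
  warp <- function(x) 2 * 2 * tan(pi * x / 2)   # prewarp at fs = 2
  p <- butter_proto_poles(order)
  z <- complex(0)
  k <- 1
  if (type == "low") {
    wc <- warp(w)
    p <- p * wc
    k <- wc^order
  } else if (type == "high") {
    wc <- warp(w)
    z <- rep(0 + 0i, order)
    k <- 1
    p <- wc / p
  } else {
    if (length(w) != 2L || w[1] >= w[2]) stop_param("need w = c(low, high)")
    w1 <- warp(w[1]); w2 <- warp(w[2])
    bw <- w2 - w1; w0 <- sqrt(w1 * w2)
    # lowpass -> bandpass transform: s -> (s^2 + w0^2) / (bw s)
    ps <- p * bw / 2
    disc <- sqrt(ps^2 - w0^2)
    p <- c(ps + disc, ps - disc)
    z <- rep(0 + 0i, order)
    k <- bw^order
  }
  dz <- bilinear_zpk(z, p, k)
  b <- Re(poly_from_roots(dz$z) * dz$k)
  a <- Re(poly_from_roots(dz$p))
  list(b = b, a = a)
}

# Direct-form II transposed IIR filtering.
iir_filter <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  y <- numeric(length(x))
  z <- numeric(n - 1)
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (n > 2) z[1:(n - 2)] <- b[2:(n - 1)] * xi + z[2:(n - 1)] - a[2:(n - 1)] * yi
    z[n - 1] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

#' Zero-phase forward-backward filtering with reflect padding
#'
#' Applies the IIR filter forward and then backward so the net phase
#' response is zero (magnitude response squared). The series is extended by
#' reflection at both ends before filtering to suppress startup transients.
#'
#' @param b,a Filter coefficients from [butter_design].
#' @param x Numeric series.
#' @param pad Number of reflected samples at each edge (default
#'   `3 * (max(length(a), length(b)) - 1)` or a caller-specified length).
#' @return Filtered series, same length as `x`.
#' @export
filtfilt_reflect <- function(b, a, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- 3L * (max(length(a), length(b)) - 1L)
  pad <- min(pad, n - 1L)
  if (pad < 1L) stop_param("series too short to filter")
  xe <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

# Kaiser window of length n with shape parameter beta.
kaiser_window <- function(n, beta) {
  k <- seq(0, n - 1)
  besselI(beta * sqrt(1 - (2 * k / (n - 1) - 1)^2), 0) / besselI(beta, 0)
}

# Kaiser-windowed sinc lowpass FIR; cutoff wc in units of Nyquist.
kaiser_sinc_fir <- function(n_taps, wc, beta = 7.8562) {
  m <- n_taps - 1
  k <- seq(0, m) - m / 2
  h <- wc * ifelse(k == 0, 1, sin(pi * wc * k) / (pi * wc * k))
  h * kaiser_window(n_taps, beta)
}

#' Rational-ratio resampling with Kaiser anti-alias filtering
#'
#' Upsample by `L`, filter with a Kaiser-windowed sinc lowpass at the
#' narrower of the two Nyquist limits, then decimate by `M`, where
#' `L/M = fs_out/fs_in` in lowest terms. Output length is
#' `round(n * fs_out / fs_in)`.
#'
#' @param x Numeric series sampled at `fs_in`.
#' @param fs_in,fs_out Input and output sampling rates (Hz);
#'   `fs_out <= fs_in`.
#' @return Numeric series at `fs_out`.
#' @export
resample_series <- function(x, fs_in, fs_out) {
  if (fs_out > fs_in) stop_param("`fs_out` must not exceed `fs_in`")
  if (fs_out == fs_in) return(x)
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  # work in integer rate units (handles e.g. 160 -> 128 as 4:5)
  r <- g(round(fs_in), round(fs_out))
  L <- round(fs_out) / r
  M <- round(fs_in) / r
  n <- length(x)
  up <- numeric(n * L)
  up[seq(1, n * L, by = L)] <- x * L
  wc <- min(1 / L, 1 / M)            # in units of the upsampled Nyquist
  n_taps <- 2L * 10L * max(L, M) + 1L
  h <- kaiser_sinc_fir(n_taps, wc)
  delay <- (n_taps - 1L) / 2L
  y <- conv_causal(c(up, numeric(delay)), h)[-seq_len(delay)]
  y[seq(1, by = M, length.out = round(n * fs_out / fs_in))]
}

#' Analytic-signal amplitude envelope via the FFT Hilbert transform
#'
#' @param x Real series (band-limited for a meaningful envelope).
#' @return Non-negative envelope, same length as `x`.
#' @export
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}
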