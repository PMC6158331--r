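# IIR filter design and application.
#
# Classic bilinear-transform Butterworth design plus a standard biquad notch.
# Filtering is done with stats::filter (C-level) in two stages: the FIR part
# by convolution and the AR part by recursion, so long recordings stay fast.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p) * rt
  p
}

#' Design a digital Butterworth filter
#'
#' Bilinear transform of the analog Butterworth prototype, with frequency
#' prewarping. Returns transfer-function coefficients normalized so that
#' `a[1] == 1`.
#'
#' @param order Filter order (number of poles).
#' @param cutoff_hz Cutoff frequency (-3 dB point) in Hz.
#' @param fs Sampling rate in Hz.
#' @param type `"low"` or `"high"`.
#' @return A list with numerator `b` and denominator `a`.
#' @export
butter_design <- function(order, cutoff_hz, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (!is_count(order) || order < 1) stopf("order must be a positive integer")
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stopf("cutoff_hz must lie in (0, fs/2)")
  }
  n <- as.integer(order)
  wc <- 2 * fs * tan(pi * cutoff_hz / fs)          # prewarped analog cutoff
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n)) # unit-cutoff poles, LHP
  if (type == "low") {
    pa <- wc * proto
    za <- complex(0)
    ka <- wc^n
  } else {
    pa <- wc / proto
    za <- rep(0 + 0i, n)
    ka <- 1
  }
  fs2 <- 2 * fs
  pd <- (fs2 + pa) / (fs2 - pa)
  zd <- if (length(za)) (fs2 + za) / (fs2 - za) else complex(0)
  # bilinear maps infinity to z = -1; pad zeros there
  zd <- c(zd, rep(-1 + 0i, n - length(zd)))
  kd <- ka * Re(prod(fs2 - za) / prod(fs2 - pa))
  b <- Re(poly_from_roots(zd)) * kd
  a <- Re(poly_from_roots(pd))
  list(b = b / a[1], a = a / a[1])
}

#' Design a second-order notch filter
#'
#' Standard constrained biquad with unit gain away from the notch.
#'
#' @param f0 Notch center frequency in Hz.
#' @param fs Sampling rate in Hz.
#' @param halfwidth_hz Half of the -3 dB bandwidth, in Hz.
#' @return A list with `b` and `a`.
#' @export
notch_design <- function(f0, fs, halfwidth_hz = 2) {
  if (f0 <= 0 || f0 >= fs / 2) stopf("f0 must lie in (0, fs/2)")
  w0 <- 2 * pi * f0 / fs
  bw <- 2 * halfwidth_hz
  q <- f0 / bw
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Steady-state initial conditions for an IIR filter
#'
#' The direct-form-II-transposed state for which a unit-step input yields a
#' step output at the filter's DC gain immediately (no startup transient).
#' Scaled by the first sample, it initializes [filtfilt()].
#'
#' @param b,a Transfer-function coefficients.
#' @return State vector of length `max(length(a), length(b)) - 1`.
#' @export
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  if (n == 1) return(numeric(0))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[2:n] / a[1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  solve(diag(n - 1) - t(comp), b[2:n] - a[2:n] * b[1])
}

#' Apply an IIR filter (single pass)
#'
#' Direct-form II transposed; zero initial conditions by default.
#'
#' @param b,a Transfer-function coefficients (`a[1]` must be 1).
#' @param x Numeric signal.
#' @param zi Optional initial filter state.
#' @return Filtered signal, same length as `x`.
#' @export
iir_filter <- function(b, a, x, zi = NULL) {
  .iir_df2t_cpp(b, a, x, zi %||% numeric(0))
}

#' Zero-phase (forward-backward) filtering
#'
#' Filters forwards then backwards with odd-reflection edge padding and
#' steady-state initial conditions scaled to the edge samples, so that
#' constant inputs produce no startup transient. The magnitude response is
#' applied twice; the phase response cancels.
#'
#' @inheritParams iir_filter
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt <- function(b, a, x) {
  n <- length(x)
  pad <- 3L * (max(length(a), length(b)) - 1L)
  if (pad >= n) pad <- n - 1L
  if (pad > 0) {
    pre <- 2 * x[1] - x[seq(pad + 1, 2)]
    post <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xx <- c(pre, x, post)
  } else {
    xx <- x
  }
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, xx, zi * xx[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  if (pad > 0) y <- y[(pad + 1):(pad + n)]
  y
}

#' Analytic Butterworth magnitude response
#'
#' `|H(f)| = 1 / sqrt(1 + (f/fc)^(2n))` for the analog prototype; used as an
#' independent check of attenuation in tests.
#' @param f Frequency in Hz.
#' @param fc Cutoff in Hz.
#' @param order Filter order.
#' @export
butter_magnitude <- function(f, fc, order) {
  1 / sqrt(1 + (f / fc)^(2 * order))
}
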