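# The ten per-epoch features: mean, mean absolute deviation, variance,
# skewness, kurtosis, line length, lag-1 autocorrelation, beta and gamma
# band power, and the gamma/(alpha+beta) power ratio.
#
# Conventions (fixed, because the order doubles as the embedded feature
# index): population (1/N) moments, non-excess kurtosis (Gaussian -> 3),
# half-open bands alpha [7,13), beta [13,30), gamma [30,50].

#' Names of the ten features, in embedded index order
#' @export
feature_names <- function() {
  c("mean", "mad", "variance", "skewness", "kurtosis", "line_length",
    "autocorrelation", "bp_beta", "bp_gamma", "power_ratio")
}

#' Line length of a signal
#'
#' Sum of absolute differences between successive samples; sensitive to both
#' amplitude and frequency changes and cheap enough for embedded use.
#'
#' @param x Numeric vector with at least two samples.
#' @return Non-negative scalar.
#' @export
line_length <- function(x) {
  if (length(x) < 2) stopf("line_length needs at least 2 samples")
  sum(abs(diff(x)))
}

#' Moment features of an epoch
#'
#' Population-convention moments: variance with the 1/N divisor, skewness
#' `m3/m2^1.5`, non-excess kurtosis `m4/m2^2`. For a zero-variance epoch,
#' skewness and kurtosis are returned as 0 and the result is flagged
#' degenerate.
#'
#' @param x Numeric vector with at least two samples.
#' @return Named numeric vector `(mean, mad, variance, skewness, kurtosis)`
#'   with attribute `degenerate`.
#' @export
moment_features <- function(x) {
  if (length(x) < 2) stopf("moment_features needs at least 2 samples")
  n <- length(x)
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  out <- c(mean = mu, mad = mean(abs(d)), variance = m2,
           skewness = 0, kurtosis = 0)
  degenerate <- m2 <= 0
  if (!degenerate) {
    out["skewness"] <- mean(d^3) / m2^1.5
    out["kurtosis"] <- mean(d^4) / m2^2
  }
  attr(out, "degenerate") <- degenerate
  out
}

#' Lag-1 normalized autocorrelation
#'
#' `r1 = sum((x_k - xbar)(x_{k+1} - xbar)) / sum((x_k - xbar)^2)`; 0 for a
#' zero-variance epoch.
#'
#' @param x Numeric vector with at least two samples.
#' @param lag Lag in samples (default 1, the cheapest embedded choice).
#' @return Scalar in about [-1, 1].
#' @export
autocorrelation <- function(x, lag = 1L) {
  if (length(x) < 2) stopf("autocorrelation needs at least 2 samples")
  d <- x - mean(x)
  s <- sum(d^2)
  if (s <= 0) return(0)
  n <- length(x)
  sum(d[seq_len(n - lag)] * d[seq_len(n - lag) + lag]) / s
}

# Hann-tapered one-sided periodogram as a power spectral density
# (signal^2/Hz). Returned with bin frequencies.
periodogram_psd <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
  xw <- (x - mean(x)) * w
  X <- stats::fft(xw)
  nb <- floor(n / 2) + 1L
  p <- (Mod(X[seq_len(nb)])^2) / (fs * sum(w^2))
  # fold negative frequencies (all bins except DC and, for even n, Nyquist)
  inner <- 2:(nb - 1L)
  if (n %% 2 == 1) inner <- 2:nb
  p[inner] <- 2 * p[inner]
  list(freq = (seq_len(nb) - 1) * fs / n, psd = p)
}

#' Average band power of an epoch
#'
#' Integrates a Hann-tapered periodogram over `[f_lo, f_hi)` (or a closed
#' upper edge with `closed_upper = TRUE`), giving power in signal-squared
#' units. The epoch mean is removed first.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param f_lo,f_hi Band edges in Hz, within `[0, fs/2]`.
#' @param closed_upper Include the `f_hi` bin.
#' @return Non-negative scalar.
#' @export
band_power <- function(x, fs, f_lo, f_hi, closed_upper = FALSE) {
  if (!(f_lo >= 0 && f_lo < f_hi && f_hi <= fs / 2)) {
    stopf("band [%g, %g] must lie within [0, fs/2]", f_lo, f_hi)
  }
  pg <- periodogram_psd(x, fs)
  df <- pg$freq[2] - pg$freq[1]
  sel <- pg$freq >= f_lo & (if (closed_upper) pg$freq <= f_hi
                            else pg$freq < f_hi)
  sum(pg$psd[sel]) * df
}

#' Gamma over (alpha + beta) band-power ratio
#'
#' `bp(30-50] / (bp[7-13) + bp[13-30) + eps)`. Elevated at low-voltage fast
#' activity onset, where gamma power rises while alpha/beta power falls.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz (must exceed 100).
#' @param eps Floor preventing division by zero, in signal-squared units.
#' @return Non-negative scalar.
#' @export
power_ratio <- function(x, fs, eps = 1e-12) {
  if (fs / 2 <= 50) stopf("power_ratio needs fs/2 > 50")
  pg <- periodogram_psd(x, fs)
  df <- pg$freq[2] - pg$freq[1]
  bp <- function(lo, hi, closed) {
    sel <- pg$freq >= lo & (if (closed) pg$freq <= hi else pg$freq < hi)
    sum(pg$psd[sel]) * df
  }
  bp(30, 50, TRUE) / (bp(7, 13, FALSE) + bp(13, 30, FALSE) + eps)
}

#' Ten-feature vector for one epoch
#'
#' @param x Numeric vector (one epoch, one channel).
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector of length 10, ordered as
#'   [feature_names()].
#' @export
feature_vector <- function(x, fs) {
  mo <- moment_features(x)
  out <- c(mo["mean"], mo["mad"], mo["variance"], mo["skewness"],
           mo["kurtosis"],
           line_length = line_length(x),
           autocorrelation = autocorrelation(x),
           bp_beta = band_power(x, fs, 13, 30),
           bp_gamma = band_power(x, fs, 30, 50, closed_upper = TRUE),
           power_ratio = power_ratio(x, fs))
  names(out) <- feature_names()
  out
}

#' Feature matrix for an epoch set
#'
#' One ten-entry feature vector per (epoch, channel). Artifact-flagged
#' epochs keep their mask; downstream training excludes them.
#'
#' @param epoch_set An `epoch_set` from [epoch_recording()].
#' @return A `feature_set`: list with `features` (epochs x channels x 10
#'   array), plus labels, mask and timing carried over from the epoch set.
#' @export
feature_matrix <- function(epoch_set) {
  n_ep <- dim(epoch_set$data)[1]
  nch <- dim(epoch_set$data)[2]
  feats <- array(0, c(n_ep, nch, 10L),
                 dimnames = list(NULL, NULL, feature_names()))
  for (ch in seq_len(nch)) {
    for (e in seq_len(n_ep)) {
      feats[e, ch, ] <- feature_vector(epoch_set$data[e, ch, ], epoch_set$fs)
    }
  }
  structure(
    list(features = feats, labels = epoch_set$labels,
         artifact_mask = epoch_set$artifact_mask,
         epoch_start_s = epoch_set$epoch_start_s,
         epoch_len_s = epoch_set$epoch_len_s,
         annotations = epoch_set$annotations,
         block_id = epoch_set$block_id, fs = epoch_set$fs),
    class = "feature_set")
}

#' Write a feature set to CSV
#'
#' Long format: block, epoch, channel, start time, label, artifact flag and
#' the ten features under their fixed embedded-order names.
#'
#' @param fset A `feature_set`.
#' @param path Output CSV path.
#' @export
write_feature_csv <- function(fset, path) {
  n_ep <- dim(fset$features)[1]
  nch <- dim(fset$features)[2]
  rows <- do.call(rbind, lapply(seq_len(nch), function(ch) {
    cbind(data.frame(block_id = fset$block_id, epoch = seq_len(n_ep),
                     channel = ch, start_s = fset$epoch_start_s,
                     ictal = fset$labels,
                     artifact = fset$artifact_mask[, ch]),
          as.data.frame(fset$features[, ch, , drop = TRUE]))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
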