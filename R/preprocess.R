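# Preprocessing: re-referencing, resampling, filtering, epoching, artifact
# rejection.

#' Preprocessing configuration
#'
#' @param target_fs Working sampling rate in Hz; higher-rate recordings are
#'   decimated to this.
#' @param hp_cutoff High-pass cutoff in Hz (removes slow drifts).
#' @param hp_order High-pass Butterworth order.
#' @param powerline_hz Powerline frequency for the band-stop notch.
#' @param bandstop_halfwidth Notch half-width in Hz.
#' @param lp_cutoff Low-pass cutoff in Hz (removes >50 Hz burst content).
#' @param lp_order Low-pass Butterworth order.
#' @param epoch_len_s Epoch length in seconds (non-overlapping windows).
#' @param artifact_low_var_frac An epoch is flagged when its variance falls
#'   below this fraction of the channel's mean epoch variance.
#' @param artifact_amp_mult An epoch is flagged when its peak absolute
#'   amplitude exceeds this multiple of the channel's standard deviation.
#' @param zero_phase Apply filters forward-backward (offline pipeline). Set
#'   `FALSE` for the causal variant used by the embedded simulation.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_fs = 256, hp_cutoff = 0.5, hp_order = 2,
                              powerline_hz = 50, bandstop_halfwidth = 2,
                              lp_cutoff = 50, lp_order = 6, epoch_len_s = 1,
                              artifact_low_var_frac = 0.1,
                              artifact_amp_mult = 10, zero_phase = TRUE) {
  cfg <- structure(as.list(environment()), class = "preprocess_config")
  if (!(cfg$hp_cutoff < cfg$lp_cutoff && cfg$lp_cutoff < cfg$target_fs / 2)) {
    stopf("need hp_cutoff < lp_cutoff < target_fs/2")
  }
  if (cfg$epoch_len_s <= 0) stopf("epoch_len_s must be positive")
  cfg
}

#' Local re-referencing
#'
#' For each electrode group, subtracts the per-sample mean of the group's
#' channels from each channel in the group.
#'
#' @param recording An `ieeg_recording` with `electrode_groups` set.
#' @return The re-referenced recording.
#' @export
local_rereference <- function(recording) {
  for (g in recording$electrode_groups) {
    if (length(g) == 0) stopf("electrode group with zero channels")
    m <- colMeans(recording$signal[g, , drop = FALSE])
    recording$signal[g, ] <- sweep(recording$signal[g, , drop = FALSE], 2, m)
  }
  recording
}

#' Decimate a recording to a lower sampling rate
#'
#' Anti-alias low-pass (zero-phase, 8th-order Butterworth at 0.45 times the
#' target rate) followed by integer-factor decimation. Annotations are in
#' seconds and are unchanged.
#'
#' @param recording An `ieeg_recording`.
#' @param target_fs Target rate; must divide the original rate.
#' @return The resampled recording.
#' @export
resample_recording <- function(recording, target_fs = 256) {
  fs <- recording$fs
  if (target_fs > fs) stopf("upsampling is not supported")
  if (target_fs == fs) return(recording)
  q <- fs / target_fs
  if (abs(q - round(q)) > 1e-9) {
    stopf("original rate must be an integer multiple of target_fs")
  }
  q <- as.integer(round(q))
  aa <- butter_design(8, 0.45 * target_fs, fs, "low")
  keep <- seq(1, ncol(recording$signal), by = q)
  out <- matrix(0, nrow(recording$signal), length(keep))
  for (ch in seq_len(nrow(recording$signal))) {
    out[ch, ] <- filtfilt(aa$b, aa$a, recording$signal[ch, ])[keep]
  }
  recording$signal <- out
  recording$fs <- target_fs
  recording
}

#' High-pass, notch, and low-pass filtering
#'
#' Applies, in order: a high-pass at `hp_cutoff`, a band-stop notch at the
#' powerline frequency, and a low-pass Butterworth of order `lp_order` at
#' `lp_cutoff`. Zero-phase by default.
#'
#' @param recording An `ieeg_recording` at the working rate.
#' @param config A [preprocess_config()].
#' @return The filtered recording.
#' @export
filter_chain <- function(recording, config = preprocess_config()) {
  fs <- recording$fs
  if (fs / 2 <= config$lp_cutoff) stopf("lp_cutoff must be below Nyquist")
  hp <- butter_design(config$hp_order, config$hp_cutoff, fs, "high")
  bs <- notch_design(config$powerline_hz, fs, config$bandstop_halfwidth)
  lp <- butter_design(config$lp_order, config$lp_cutoff, fs, "low")
  apply1 <- if (config$zero_phase) filtfilt else iir_filter
  for (ch in seq_len(nrow(recording$signal))) {
    x <- recording$signal[ch, ]
    x <- apply1(hp$b, hp$a, x)
    x <- apply1(bs$b, bs$a, x)
    x <- apply1(lp$b, lp$a, x)
    recording$signal[ch, ] <- x
  }
  recording
}

#' Cut a recording into labeled non-overlapping epochs
#'
#' Epochs are contiguous `epoch_len_s` windows; a trailing partial window is
#' dropped. An epoch is labeled ictal iff its half-open interval
#' `[start, start + epoch_len_s)` intersects a seizure annotation.
#'
#' @param recording An `ieeg_recording`.
#' @param epoch_len_s Epoch length in seconds.
#' @param block_id Identifier carried through to evaluation.
#' @return An `epoch_set`: list with `data` (epochs x channels x samples
#'   array), logical `labels`, `artifact_mask` (epochs x channels, filled by
#'   [reject_artifacts()]), `epoch_start_s`, `fs`, `annotations`, `block_id`.
#' @export
epoch_recording <- function(recording, epoch_len_s = 1, block_id = 1L) {
  fs <- recording$fs
  spe <- round(epoch_len_s * fs)
  n_ep <- floor(ncol(recording$signal) / spe)
  if (n_ep < 1) stopf("recording shorter than one epoch")
  nch <- nrow(recording$signal)
  dat <- array(0, c(n_ep, nch, spe))
  for (e in seq_len(n_ep)) {
    dat[e, , ] <- recording$signal[, ((e - 1) * spe + 1):(e * spe), drop = FALSE]
  }
  starts <- (seq_len(n_ep) - 1) * epoch_len_s
  sz <- seizure_annotations(recording)
  labels <- rep(FALSE, n_ep)
  for (i in seq_len(nrow(sz))) {
    labels <- labels | (starts < sz$end_s[i] &
                          (starts + epoch_len_s) > sz$start_s[i])
  }
  structure(
    list(data = dat, labels = labels,
         artifact_mask = matrix(FALSE, n_ep, nch),
         epoch_start_s = starts, epoch_len_s = epoch_len_s, fs = fs,
         annotations = recording$annotations, block_id = block_id,
         channel_names = recording$channel_names),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels (%g s @ %g Hz), %d ictal, %d flagged\n",
              dim(x$data)[1], dim(x$data)[2], x$epoch_len_s, x$fs,
              sum(x$labels), sum(apply(x$artifact_mask, 1, any))))
  invisible(x)
}

#' Flag artifact epochs
#'
#' Per channel, an epoch is flagged when (a) its variance is below
#' `artifact_low_var_frac` times the channel's mean epoch variance, (b) its
#' peak absolute amplitude exceeds `artifact_amp_mult` times the channel's
#' block standard deviation, or (c) its peak-to-peak amplitude is near
#' numeric zero. Flagged epochs are excluded from training and scored as
#' non-detections downstream.
#'
#' @param epoch_set An `epoch_set`.
#' @param config A [preprocess_config()].
#' @return The epoch set with `artifact_mask` filled.
#' @export
reject_artifacts <- function(epoch_set, config = preprocess_config()) {
  n_ep <- dim(epoch_set$data)[1]
  nch <- dim(epoch_set$data)[2]
  if (n_ep < 2) stopf("need at least 2 epochs per channel")
  for (ch in seq_len(nch)) {
    x <- epoch_set$data[, ch, , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = n_ep)
    ep_var <- apply(x, 1, stats::var)
    ep_max <- apply(abs(x), 1, max)
    ep_ptp <- apply(x, 1, function(v) diff(range(v)))
    block_sd <- stats::sd(as.numeric(x))
    flag <- ep_var < config$artifact_low_var_frac * mean(ep_var) |
      ep_max > config$artifact_amp_mult * block_sd |
      ep_ptp < 1e-9
    epoch_set$artifact_mask[, ch] <- flag
  }
  epoch_set
}

#' Full preprocessing of one raw recording
#'
#' Re-reference, resample to the working rate, filter, epoch, and flag
#' artifacts.
#'
#' @param recording An `ieeg_recording`.
#' @param config A [preprocess_config()].
#' @param block_id Identifier carried through to evaluation.
#' @return An `epoch_set`.
#' @export
preprocess_recording <- function(recording, config = preprocess_config(),
                                 block_id = 1L) {
  rec <- local_rereference(recording)
  rec <- resample_recording(rec, config$target_fs)
  rec <- filter_chain(rec, config)
  es <- epoch_recording(rec, config$epoch_len_s, block_id = block_id)
  reject_artifacts(es, config)
}
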