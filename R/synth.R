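# Synthetic multichannel iEEG generator.
#
# Emulates the statistical structure the detection pipeline assumes: 1/f
# background with an alpha rhythm, powerline contamination and slow drifts;
# one seizure per block on a small set of onset-zone channels, with one of
# three onset patterns; and artifact segments (flatline, high-amplitude
# transients) for the rejection stage to catch. It is a signal-level
# emulation, not a neural-mass model.

#' Configuration for the synthetic iEEG generator
#'
#' Defaults describe a detectable but non-trivial focal seizure in a
#' one-hour block sampled at 256 Hz; tests shorten `block_duration_s`.
#' Amplitudes are in microvolt-like units.
#'
#' @param fs Sampling rate in Hz.
#' @param block_duration_s Block length in seconds (one seizure per block).
#' @param n_channels Total channel count.
#' @param soz_channels Indices of the seizure-onset-zone channels (1-4).
#' @param onset_pattern One of `"LVFA"` (low-voltage fast activity:
#'   attenuated background plus a ramping gamma component),
#'   `"rhythmic_spiking"` (2-5 Hz biphasic transients), `"rhythmic_beta"`
#'   (strong 13-30 Hz burst).
#' @param seizure_onset_s Onset time in seconds; `NA` draws it uniformly
#'   from the middle 30-60% of the block.
#' @param seizure_duration_s Seizure length in seconds.
#' @param background_sd Standard deviation of the colored-noise background.
#' @param background_alpha_amp Amplitude of the 10 Hz background rhythm.
#' @param noise_exponent Spectral exponent of the background noise
#'   (power ~ 1/f^exponent; 0 gives white noise).
#' @param powerline_hz Powerline frequency (50 or 60).
#' @param powerline_amp Powerline sinusoid amplitude.
#' @param drift_amp Amplitude of the sub-0.5 Hz drift.
#' @param lvfa_attenuation Background multiplier during LVFA (amplitude
#'   suppression; also lowers alpha/beta power).
#' @param lvfa_gamma_amp Plateau amplitude of the LVFA gamma component.
#' @param lvfa_ramp_s Seconds over which the gamma amplitude ramps from 0
#'   to its plateau, making the first seconds genuinely harder to detect.
#' @param lvfa_amplitude_neutral If `TRUE`, the gamma plateau is rescaled
#'   per channel so total signal power is unchanged by the seizure (a pure
#'   spectral redistribution that line length is nearly blind to).
#' @param spike_rate_hz Transient rate for `"rhythmic_spiking"`.
#' @param spike_amp Transient amplitude for `"rhythmic_spiking"`.
#' @param beta_amp Burst amplitude for `"rhythmic_beta"`.
#' @param artifact_rate_per_hour Artifact segments per hour.
#' @param seed Integer seed; the same config and seed give bit-identical
#'   output.
#' @return A `synth_config` list.
#' @export
synth_config <- function(fs = 256, block_duration_s = 3600, n_channels = 4,
                         soz_channels = c(1L, 2L), onset_pattern = "LVFA",
                         seizure_onset_s = NA, seizure_duration_s = 60,
                         background_sd = 20, background_alpha_amp = 10,
                         noise_exponent = 1, powerline_hz = 50,
                         powerline_amp = 2, drift_amp = 30,
                         lvfa_attenuation = 0.4, lvfa_gamma_amp = 30,
                         lvfa_ramp_s = 10, lvfa_amplitude_neutral = FALSE,
                         spike_rate_hz = 3, spike_amp = 120, beta_amp = 40,
                         artifact_rate_per_hour = 6, seed = 1L) {
  cfg <- structure(as.list(environment()), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (!is_scalar_num(cfg$fs) || cfg$fs <= 0) stopf("fs must be positive")
  if (!is_scalar_num(cfg$block_duration_s) || cfg$block_duration_s <= 0) {
    stopf("block_duration_s must be positive")
  }
  if (!is_count(cfg$n_channels) || cfg$n_channels < 1) {
    stopf("n_channels must be a positive integer")
  }
  soz <- cfg$soz_channels
  if (length(soz) < 1 || length(soz) > 4 ||
      any(soz < 1 | soz > cfg$n_channels)) {
    stopf("soz_channels must name 1-4 channels within 1..n_channels")
  }
  if (!cfg$onset_pattern %in% c("LVFA", "rhythmic_spiking", "rhythmic_beta")) {
    stopf("unknown onset_pattern '%s'", cfg$onset_pattern)
  }
  if (!is.na(cfg$seizure_onset_s)) {
    if (cfg$seizure_onset_s <= 0 ||
        cfg$seizure_onset_s + cfg$seizure_duration_s >= cfg$block_duration_s) {
      stopf("seizure interval must lie strictly inside the block")
    }
  }
  if (cfg$artifact_rate_per_hour < 0) stopf("artifact rate must be >= 0")
  invisible(cfg)
}

# 1/f^exponent noise by FFT spectral shaping, rescaled to unit sd
colored_noise <- function(n, exponent, fs) {
  w <- stats::rnorm(n)
  if (exponent == 0) return(w)
  x <- stats::fft(w)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) * fs / n
  scale <- ifelse(f > 0, f^(-exponent / 2), 0)
  y <- Re(stats::fft(x * scale, inverse = TRUE)) / n
  y / stats::sd(y)
}

# narrowband oscillation with slow random frequency/phase modulation
wandering_tone <- function(n, fs, f_center, f_jitter = 0.02) {
  dphi <- 2 * pi * f_center / fs + stats::rnorm(n) * f_jitter
  sin(cumsum(dphi))
}

#' Generate seizure-free background iEEG
#'
#' Colored noise plus a drifting-phase alpha rhythm, a powerline sinusoid,
#' and a slow (<0.5 Hz) drift on every channel. No seizure annotation is
#' attached.
#'
#' @param config A [synth_config()].
#' @return An `ieeg_recording`.
#' @export
generate_background <- function(config) {
  validate_synth_config(config)
  n <- round(config$block_duration_s * config$fs)
  if (n < 2) stopf("block too short")
  with_seed(derive_seed(config$seed, "background"), {
    t <- (seq_len(n) - 1) / config$fs
    sig <- matrix(0, config$n_channels, n)
    for (ch in seq_len(config$n_channels)) {
      bg <- config$background_sd *
        colored_noise(n, config$noise_exponent, config$fs)
      alpha <- config$background_alpha_amp * wandering_tone(n, config$fs, 10)
      pl <- config$powerline_amp *
        sin(2 * pi * config$powerline_hz * t + stats::runif(1, 0, 2 * pi))
      f_drift <- stats::runif(1, 0.02, 0.2)
      drift <- config$drift_amp *
        sin(2 * pi * f_drift * t + stats::runif(1, 0, 2 * pi))
      sig[ch, ] <- bg + alpha + pl + drift
    }
    groups <- list(E1 = seq_len(config$n_channels))
    new_recording(sig, fs = config$fs, electrode_groups = groups)
  })
}

#' Inject one seizure into a recording
#'
#' Rewrites the seizure interval on the seizure-onset-zone channels with the
#' configured onset pattern and appends a seizure annotation. Non-SOZ
#' channels are untouched.
#'
#' @param recording An `ieeg_recording` (typically from
#'   [generate_background()]).
#' @param config A [synth_config()].
#' @return The recording with the seizure injected and annotated.
#' @export
inject_seizure <- function(recording, config) {
  validate_synth_config(config)
  fs <- recording$fs
  dur <- recording_duration(recording)
  onset <- config$seizure_onset_s
  if (is.na(onset)) {
    onset <- with_seed(derive_seed(config$seed, "onset"),
                       stats::runif(1, 0.3 * dur, 0.6 * dur))
  }
  if (onset <= 0 || onset + config$seizure_duration_s >= dur) {
    stopf("seizure interval must lie strictly inside the block")
  }
  if (config$seizure_duration_s == 0) {
    return(add_annotation(recording, "seizure", onset, onset))
  }
  i0 <- floor(onset * fs) + 1L
  i1 <- min(floor((onset + config$seizure_duration_s) * fs), ncol(recording$signal))
  idx <- i0:i1
  nwin <- length(idx)
  tw <- (seq_len(nwin) - 1) / fs
  with_seed(derive_seed(config$seed, "seizure"), {
    for (ch in config$soz_channels) {
      bg <- recording$signal[ch, idx]
      seg <- switch(
        config$onset_pattern,
        LVFA = {
          amp <- config$lvfa_gamma_amp
          if (config$lvfa_amplitude_neutral) {
            a <- config$lvfa_attenuation
            amp <- sqrt(2 * (1 - a^2)) * stats::sd(bg)
          }
          ramp <- pmin(tw / max(config$lvfa_ramp_s, 1e-9), 1)
          config$lvfa_attenuation * bg +
            amp * ramp * wandering_tone(nwin, fs, 40, 0.06)
        },
        rhythmic_spiking = {
          # periodic biphasic sharp transients at spike_rate_hz
          period <- round(fs / config$spike_rate_hz)
          shape_t <- seq(-0.05, 0.05, by = 1 / fs)
          shape <- -shape_t * exp(-(shape_t / 0.015)^2)
          shape <- shape / max(abs(shape))
          train <- numeric(nwin)
          starts <- seq(1, nwin - length(shape), by = period)
          jit <- stats::rnorm(length(starts), 0, 0.1)
          for (j in seq_along(starts)) {
            s <- starts[j]
            train[s:(s + length(shape) - 1)] <-
              train[s:(s + length(shape) - 1)] +
              (1 + jit[j]) * config$spike_amp * shape
          }
          bg + train
        },
        rhythmic_beta = {
          ramp <- pmin(tw / 2, 1)
          bg + config$beta_amp * ramp * wandering_tone(nwin, fs, 20, 0.03)
        },
        stopf("unknown onset_pattern '%s'", config$onset_pattern))
      recording$signal[ch, idx] <- seg
    }
  })
  add_annotation(recording, "seizure", onset,
                 onset + config$seizure_duration_s)
}

#' Inject artifact segments into a recording
#'
#' Inserts flatline segments (near-zero variance) and short high-amplitude
#' transients (>10x channel standard deviation), each annotated as
#' `"artifact"`. Artifacts never overlap the seizure interval.
#'
#' @param recording An `ieeg_recording`.
#' @param config A [synth_config()].
#' @return The recording with artifacts injected and annotated.
#' @export
inject_artifacts <- function(recording, config) {
  validate_synth_config(config)
  fs <- recording$fs
  dur <- recording_duration(recording)
  n_art <- round(config$artifact_rate_per_hour * dur / 3600)
  if (n_art == 0) return(recording)
  sz <- seizure_annotations(recording)
  blocked <- if (nrow(sz)) {
    cbind(pmax(sz$start_s - 10, 0), pmin(sz$end_s + 10, dur))
  } else {
    matrix(numeric(0), 0, 2)
  }
  overlaps <- function(a0, a1) {
    nrow(blocked) > 0 && any(a0 < blocked[, 2] & a1 > blocked[, 1])
  }
  with_seed(derive_seed(config$seed, "artifacts"), {
    ch_sd <- apply(recording$signal, 1, stats::sd)
    for (k in seq_len(n_art)) {
      kind <- if (k %% 2 == 1) "flatline" else "transient"
      len <- if (kind == "flatline") 2 else 0.25
      placed <- FALSE
      for (try in 1:50) {
        a0 <- stats::runif(1, 0, dur - len)
        a1 <- a0 + len
        if (!overlaps(a0, a1)) { placed <- TRUE; break }
      }
      if (!placed) next
      j0 <- floor(a0 * fs) + 1L
      j1 <- min(floor(a1 * fs), ncol(recording$signal))
      if (kind == "flatline") {
        recording$signal[, j0:j1] <- recording$signal[, j0]
      } else {
        pulse_ch <- sample(nrow(recording$signal), 1)
        amp <- 12 * ch_sd[pulse_ch] * sample(c(-1, 1), 1)
        half <- exp(-((seq(j0, j1) - (j0 + j1) / 2) / ((j1 - j0) / 4))^2)
        recording$signal[pulse_ch, j0:j1] <-
          recording$signal[pulse_ch, j0:j1] + amp * half
      }
      blocked <- rbind(blocked, c(a0, a1))
      recording <- add_annotation(recording, "artifact", a0, a1)
    }
    recording
  })
}

#' Generate one complete synthetic block
#'
#' Background, one seizure, and artifacts, per the config.
#' @param config A [synth_config()].
#' @return An `ieeg_recording` with one seizure annotation.
#' @export
synth_block <- function(config) {
  rec <- generate_background(config)
  rec <- inject_seizure(rec, config)
  inject_artifacts(rec, config)
}

#' Generate a multi-block synthetic dataset
#'
#' Each block gets its own seed derived from `seed`, a fresh random onset
#' time (unless fixed in `config`), and exactly one seizure.
#'
#' @param n_blocks Number of one-seizure blocks.
#' @param config Base [synth_config()]; its `seed` is overridden per block.
#' @param seed Dataset-level seed.
#' @return A list of `ieeg_recording`s.
#' @export
synth_dataset <- function(n_blocks = 8, config = synth_config(),
                          seed = config$seed) {
  lapply(seq_len(n_blocks), function(b) {
    cfg <- config
    cfg$seed <- derive_seed(seed, paste0("block", b))
    synth_block(cfg)
  })
}
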