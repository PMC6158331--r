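# Synthetic iEEG generator.

short_cfg <- function(...) {
  args <- utils::modifyList(
    list(block_duration_s = 120, seizure_onset_s = 50,
         seizure_duration_s = 30, n_channels = 2, soz_channels = 1L,
         seed = 9),
    list(...))
  do.call(synth_config, args)
}

test_that("generation is bit-identical under a fixed seed", {
  cfg <- short_cfg()
  r1 <- synth_block(cfg)
  r2 <- synth_block(cfg)
  expect_identical(r1$signal, r2$signal)
  expect_identical(r1$annotations, r2$annotations)
  r3 <- synth_block(short_cfg(seed = 10))
  expect_false(identical(r1$signal, r3$signal))
})

test_that("white-noise limit gives a flat spectrum plus the powerline peak", {
  cfg <- synth_config(block_duration_s = 60, n_channels = 1, soz_channels = 1L,
                      background_alpha_amp = 0, noise_exponent = 0,
                      drift_amp = 0, powerline_amp = 5, seed = 4)
  rec <- generate_background(cfg)
  x <- rec$signal[1, ]
  ps <- Mod(fft(x - mean(x)))^2 / length(x)
  f <- (seq_along(ps) - 1) * cfg$fs / length(ps)
  band <- function(lo, hi) mean(ps[f >= lo & f < hi])
  # flat within estimation error across well-separated bands
  expect_equal(band(5, 20), band(60, 100), tolerance = 0.15)
  # powerline peak stands out
  expect_gt(mean(ps[abs(f - 50) < 0.2]), 10 * band(40, 48))
  expect_equal(nrow(seizure_annotations(rec)), 0L)
})

test_that("default background has alpha power exceeding gamma power", {
  rec <- generate_background(short_cfg())
  x <- rec$signal[1, ]
  expect_gt(band_power(x, 256, 7, 13), band_power(x, 256, 30, 50))
})

test_that("invalid configs error", {
  expect_error(synth_config(block_duration_s = -1), "positive")
  expect_error(synth_config(soz_channels = 1:5), "1-4")
  expect_error(synth_config(soz_channels = 9, n_channels = 4), "1-4|within")
  expect_error(synth_config(onset_pattern = "nonsense"), "onset_pattern")
  expect_error(synth_config(block_duration_s = 100, seizure_onset_s = 90,
                            seizure_duration_s = 20), "inside")
})

test_that("LVFA raises the ictal power ratio on SOZ channels only", {
  cfg <- short_cfg(n_channels = 2, soz_channels = 1L)
  rec <- inject_seizure(generate_background(cfg), cfg)
  es <- epoch_recording(rec)
  pr <- function(ch) {
    sapply(seq_len(dim(es$data)[1]), function(e)
      power_ratio(es$data[e, ch, ], es$fs))
  }
  pr1 <- pr(1)
  expect_gt(mean(pr1[es$labels]), mean(pr1[!es$labels]))
  # non-SOZ channel: same generator ictal vs interictal
  pr2 <- pr(2)
  expect_lt(abs(mean(pr2[es$labels]) - mean(pr2[!es$labels])),
            3 * sd(pr2[!es$labels]))
})

test_that("all three onset patterns inject detectable spectral change", {
  for (pat in c("rhythmic_spiking", "rhythmic_beta")) {
    cfg <- short_cfg(onset_pattern = pat)
    rec <- inject_seizure(generate_background(cfg), cfg)
    es <- epoch_recording(rec)
    ll <- sapply(seq_len(dim(es$data)[1]), function(e)
      line_length(es$data[e, 1, ]))
    expect_gt(mean(ll[es$labels]), mean(ll[!es$labels]))
  }
})

test_that("zero-duration seizure changes only the annotation list", {
  cfg <- short_cfg(seizure_duration_s = 0)
  bg <- generate_background(cfg)
  rec <- inject_seizure(bg, cfg)
  expect_identical(rec$signal, bg$signal)
  expect_equal(nrow(seizure_annotations(rec)), 1L)
})

test_that("artifact injection respects rate and produces the target shapes", {
  cfg0 <- short_cfg(artifact_rate_per_hour = 0)
  rec0 <- inject_artifacts(synth_block(cfg0), cfg0)
  expect_equal(sum(rec0$annotations$label == "artifact"), 0L)

  cfg <- synth_config(block_duration_s = 600, n_channels = 1,
                      soz_channels = 1L, seizure_onset_s = 300,
                      seizure_duration_s = 30, artifact_rate_per_hour = 36,
                      seed = 2)
  rec <- synth_block(cfg)
  art <- rec$annotations[rec$annotations$label == "artifact", ]
  expect_gt(nrow(art), 0)
  # artifacts never overlap the seizure
  sz <- seizure_annotations(rec)
  expect_true(all(art$end_s <= sz$start_s | art$start_s >= sz$end_s))

  es <- epoch_recording(rec)
  ep_var <- apply(es$data[, 1, ], 1, var)
  ch_sd <- sd(rec$signal[1, ])
  flat <- art[art$end_s - art$start_s > 1, ]
  for (i in seq_len(nrow(flat))) {
    e <- floor(flat$start_s[i]) + 2L  # fully inside the flat segment
    expect_lt(ep_var[e], 0.01 * mean(ep_var))
  }
  spikes <- art[art$end_s - art$start_s < 1, ]
  hit <- vapply(seq_len(nrow(spikes)), function(i) {
    e <- floor(spikes$start_s[i]) + 1L
    any(abs(es$data[e, , ]) > 10 * ch_sd)
  }, logical(1))
  expect_true(any(hit))
})

test_that("amplitude-neutral LVFA preserves total power", {
  cfg <- short_cfg(lvfa_amplitude_neutral = TRUE, drift_amp = 0)
  bg <- generate_background(cfg)
  rec <- inject_seizure(bg, cfg)
  i <- (62 * 256):(80 * 256)  # post-ramp plateau of the gamma component
  expect_equal(var(rec$signal[1, i]), var(bg$signal[1, i]), tolerance = 0.1)
})
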