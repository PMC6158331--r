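# The ten-feature set: fixed values, brute-force oracles, invariances.

test_that("line length matches hand values and a brute-force oracle", {
  expect_equal(line_length(c(1, 1, 1, 1)), 0)
  expect_equal(line_length(c(0, 1, 0, 1)), 3)
  expect_error(line_length(1), "2 samples")

  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(256)
    brute <- 0
    for (k in 2:length(x)) brute <- brute + abs(x[k] - x[k - 1])
    expect_equal(line_length(x), brute)
  }
})

test_that("moment features use population conventions", {
  m <- moment_features(c(1, 1, 1, 1))
  expect_equal(as.numeric(m), c(1, 0, 0, 0, 0))
  expect_true(attr(m, "degenerate"))

  m2 <- moment_features(c(-1, 1, -1, 1))
  expect_equal(as.numeric(m2), c(0, 1, 1, 0, 1))
  expect_false(attr(m2, "degenerate"))

  set.seed(2)
  z <- rnorm(1e5)
  mz <- moment_features(z)
  expect_equal(mz[["skewness"]], 0, tolerance = 0.05)
  expect_equal(mz[["kurtosis"]], 3, tolerance = 0.1)
  expect_equal(mz[["variance"]], var(z) * (1e5 - 1) / 1e5)
})

test_that("autocorrelation handles alternation, noise, and sinusoids", {
  expect_equal(autocorrelation(rep(c(1, -1), 32)), -1, tolerance = 0.05)
  set.seed(3)
  expect_lt(abs(autocorrelation(rnorm(1e4))), 0.05)
  t <- (0:255) / 256
  expect_equal(autocorrelation(sin(2 * pi * t)), cos(2 * pi / 256),
               tolerance = 1e-3)
  expect_equal(autocorrelation(rep(5, 10)), 0)
})

test_that("band power integrates the periodogram correctly", {
  fs <- 256
  t <- (0:(fs - 1)) / fs
  x <- sin(2 * pi * 20 * t)
  expect_equal(band_power(x, fs, 13, 30), 0.5, tolerance = 0.02)
  expect_lt(band_power(rep(3, fs), fs, 13, 30), 1e-20)
  expect_error(band_power(x, fs, 100, 200), "fs/2")

  # white noise: power ~ sigma^2 * bandwidth / nyquist
  set.seed(4)
  sims <- replicate(200, band_power(rnorm(fs, sd = 2), fs, 13, 30))
  expect_equal(mean(sims), 4 * (30 - 13) / (fs / 2), tolerance = 0.05)
})

test_that("power ratio behaves at spectral extremes and on white noise", {
  fs <- 256
  t <- (0:(fs - 1)) / fs
  expect_lt(power_ratio(sin(2 * pi * 10 * t), fs), 0.05)
  expect_gt(power_ratio(sin(2 * pi * 40 * t), fs), 10)

  # flat spectrum: the ratio of mean band powers equals the bin-count
  # ratio; with 1 Hz bins, gamma [30, 50] holds 21 bins and alpha+beta
  # [7, 30) holds 23 (comparing mean powers avoids the Jensen inflation
  # that a mean of per-epoch ratios would suffer at this bin count)
  set.seed(5)
  sims <- replicate(400, {
    x <- rnorm(fs)
    c(g = band_power(x, fs, 30, 50, closed_upper = TRUE),
      ab = band_power(x, fs, 7, 13) + band_power(x, fs, 13, 30))
  })
  expect_equal(mean(sims["g", ]) / mean(sims["ab", ]), 21 / 23,
               tolerance = 0.05)
  # the per-epoch ratio itself sits near that value
  set.seed(5)
  ratios <- replicate(200, power_ratio(rnorm(fs), fs))
  expect_gt(median(ratios), 0.6)
  expect_lt(median(ratios), 1.2)
})

test_that("feature matrix has fixed shape and is recomputable per element", {
  fx <- tiny_blocks()$blocks[[1]]
  expect_equal(dim(fx$features)[3], 10L)
  expect_equal(dimnames(fx$features)[[3]], feature_names())

  es <- tiny_blocks()$epochs[[1]]
  for (e in c(1, 17)) {
    expect_equal(fx$features[e, 1, ],
                 feature_vector(es$data[e, 1, ], es$fs))
  }
})

test_that("features obey scale and shift equivariances", {
  set.seed(6)
  x <- rnorm(256)
  fs <- 256
  c0 <- feature_vector(x, fs)
  c3 <- feature_vector(3 * x, fs)
  expect_equal(c3[["line_length"]], 3 * c0[["line_length"]])
  expect_equal(c3[["mad"]], 3 * c0[["mad"]])
  expect_equal(c3[["variance"]], 9 * c0[["variance"]])
  expect_equal(c3[["bp_gamma"]], 9 * c0[["bp_gamma"]])
  for (f in c("skewness", "kurtosis", "autocorrelation", "power_ratio")) {
    expect_equal(c3[[f]], c0[[f]], tolerance = 1e-9)
  }
  sh <- feature_vector(x + 100, fs)
  expect_equal(sh[["mean"]], c0[["mean"]] + 100)
  expect_equal(sh[-1], c0[-1], tolerance = 1e-6)
})
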