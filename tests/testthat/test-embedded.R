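# Embedded simulation: gain, ADC, fixed point, serialization, voting.

test_that("gain follows the full-scale formula and scales linearly", {
  expect_equal(compute_gain(0.5, 10, 2.5, 10), 4096)
  expect_equal(compute_gain(1.0, 10, 2.5, 10), 8192)
  expect_error(compute_gain(0, 10, 2.5, 10), "positive")
})

test_that("the quantizer bounds error, clips rails, and stays monotone", {
  set.seed(18)
  x <- rnorm(5000)
  cfg <- embedded_config()
  q <- adc_quantize(x, cfg)
  rec <- adc_dequantize(q$codes, q$lsb, q$full_scale)
  in_range <- abs(x) < q$full_scale
  expect_true(all(abs(rec[in_range] - x[in_range]) <= q$lsb / 2 + 1e-12))

  # +/- sigma_mult * sd maps to the rails
  ext <- c(-50 * sd(x), 50 * sd(x))
  qe <- adc_quantize(c(x, ext), cfg, signal_std = sd(x))
  expect_equal(qe$codes[length(qe$codes) - 1], 0L)
  expect_equal(qe$codes[length(qe$codes)], 2^cfg$adc_bits - 1L)

  xs <- sort(x)
  qs <- adc_quantize(xs, cfg, signal_std = sd(x))
  expect_true(all(diff(qs$codes) >= 0))
})

test_that("fixed-point features: exact zeros, wide-word limit, 16-bit sanity", {
  cfg <- embedded_config()
  const <- rep(512L, 256)
  fv <- fixed_point_features(const, 256, cfg)
  expect_equal(fv[["line_length"]], 0)
  expect_equal(fv[["variance"]], 0)

  es <- tiny_blocks()$epochs[[1]]
  wide <- embedded_config(word_bits = 52)
  x <- es$data[30, 1, ]
  q <- adc_quantize(x, wide)
  fx <- fixed_point_features(q$codes, es$fs, wide, q$lsb)
  fl <- feature_vector(adc_dequantize(q$codes, q$lsb, q$full_scale), es$fs)
  expect_equal(as.numeric(fx), as.numeric(fl), tolerance = 1e-6)

  # 16-bit features remain strongly correlated with the float pipeline
  fb <- feature_matrix(es)
  eb <- embedded_featurize(es, cfg)
  for (f in c("line_length", "variance", "power_ratio", "bp_gamma")) {
    expect_gt(cor(fb$features[, 1, f], eb$features[, 1, f]), 0.95)
  }
})

test_that("serialization uses 5 bytes per node and round-trips predictions", {
  m <- tiny_forest()
  sf <- serialize_forest(m)
  sz <- serialized_size(sf)
  expect_equal(sz$payload, 5 * sf$n_nodes)
  expect_equal(sz$total, sz$header + 5 * sf$n_nodes)

  # predictions under quantized thresholds are the round-trip baseline:
  # re-serializing the deserialized forest is exact
  d <- deserialize_forest(sf)
  tr <- tiny_train()
  d2 <- deserialize_forest(serialize_forest(d, scales = sf$scales))
  expect_equal(rf_score(d2, tr$x), rf_score(d, tr$x))
  # quantization moves few votes on points away from the thresholds
  expect_gt(cor(rf_score(d, tr$x), rf_score(m, tr$x)), 0.999)

  # topology is preserved exactly; thresholds to 16-bit quantization
  for (t in seq_along(m$trees)) {
    expect_identical(d$trees[[t]]$feature, m$trees[[t]]$feature)
    expect_identical(d$trees[[t]]$right, m$trees[[t]]$right)
    expect_identical(d$trees[[t]]$label, m$trees[[t]]$label)
    int <- m$trees[[t]]$feature >= 0
    scale <- sf$scales[m$trees[[t]]$feature[int] + 1]
    expect_true(all(abs(d$trees[[t]]$threshold[int] -
                          m$trees[[t]]$threshold[int]) <= scale / 2 + 1e-12))
  }

  # file round trip
  path <- tempfile(fileext = ".bin")
  write_forest_binary(sf, path)
  sf2 <- read_forest_binary(path)
  expect_identical(sf2$bytes, sf$bytes)
  expect_equal(rf_score(deserialize_forest(sf2), tr$x), rf_score(d, tr$x))

  expect_error(serialize_forest(m, scales = rep(1e-300, 10)), "16-bit")
})

test_that("short-circuit vote equals the full majority and stops early", {
  m <- tiny_forest()
  sf <- deserialize_forest(serialize_forest(m))
  cfg <- embedded_config(stop_after_negatives = ceiling(length(m$trees) / 2))
  tr <- tiny_train()
  set.seed(19)
  rows <- sample(nrow(tr$x), 60)
  full <- rf_score(m, tr$x[rows, , drop = FALSE])
  for (k in seq_along(rows)) {
    v <- shortcircuit_vote(sf, tr$x[rows[k], ], cfg)
    expect_equal(v$decision, as.integer(full[k] > 0.5))
    expect_lte(v$trees_evaluated, length(m$trees))
  }
})

test_that("an all-negative input stops after exactly stop_after_negatives trees", {
  # forest of stumps that always vote negative for x below the threshold
  stump <- list(feature = c(0L, -1L, -1L), threshold = c(10, 0, 0),
                right = c(2L, -1L, -1L), label = c(-1L, 0L, 1L))
  forest <- structure(list(trees = rep(list(stump), 100)), class = "rf_model")
  cfg <- embedded_config(stop_after_negatives = 50)
  v <- shortcircuit_vote(forest, c(0, rep(0, 9)), cfg)
  expect_equal(v$decision, 0L)
  expect_equal(v$trees_evaluated, 50L)
  expect_equal(v$node_visits, 50L)  # one internal node per stump

  counts <- node_eval_count(forest, matrix(0, 3, 10), cfg)
  expect_equal(counts, rep(50L, 3))
})
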