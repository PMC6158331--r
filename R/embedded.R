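# Simulation of the microcontroller deployment: analog gain + ADC
# quantization, 16-bit fixed-point feature truncation, the 5-byte-per-node
# forest serialization, and short-circuit majority voting.

#' Embedded deployment configuration
#'
#' @param adc_bits ADC resolution in bits.
#' @param vref ADC reference voltage in volts.
#' @param word_bits Fixed-point arithmetic width for feature values.
#' @param sigma_mult Full scale covers plus/minus this many signal standard
#'   deviations (clipping beyond suppresses artifacts).
#' @param stop_after_negatives Stop vote counting once this many trees have
#'   voted non-seizure.
#' @export
embedded_config <- function(adc_bits = 10, vref = 2.5, word_bits = 16,
                            sigma_mult = 10, stop_after_negatives = 50) {
  if (adc_bits > word_bits) stopf("adc_bits must not exceed word_bits")
  if (sigma_mult <= 0) stopf("sigma_mult must be positive")
  structure(as.list(environment()), class = "embedded_config")
}

#' Analog front-end gain
#'
#' `gain = (2 * sigma_mult * std * 2^adc_bits) / vref`, chosen so that
#' plus/minus `sigma_mult` standard deviations of the test signal span the
#' ADC full scale (with the default `sigma_mult = 10`, the leading factor
#' is the conventional 20).
#'
#' @param signal_std Standard deviation of the signal to be acquired.
#' @param adc_bits ADC resolution in bits (resolution = `2^adc_bits`
#'   counts).
#' @param vref ADC reference voltage.
#' @param sigma_mult Full-scale multiple of the standard deviation.
#' @return The scalar gain.
#' @export
compute_gain <- function(signal_std, adc_bits = 10, vref = 2.5,
                         sigma_mult = 10) {
  if (!is_scalar_num(signal_std) || signal_std <= 0) {
    stopf("signal_std must be positive")
  }
  if (vref <= 0) stopf("vref must be positive")
  (2 * sigma_mult * signal_std * 2^adc_bits) / vref
}

#' Quantize a signal through the simulated ADC
#'
#' Uniform mid-rise quantizer with `2^adc_bits` levels spanning plus/minus
#' `sigma_mult` times the signal standard deviation; samples beyond the
#' rails are clipped (the stated artifact suppression). The LSB in signal
#' units is `2 * sigma_mult * std / 2^adc_bits`.
#'
#' @param signal Numeric vector (one channel).
#' @param config An [embedded_config()].
#' @param signal_std Standard deviation used for scaling; defaults to the
#'   signal's own (the "test data" convention).
#' @return List with integer `codes` in `[0, 2^adc_bits - 1]`, `lsb`,
#'   `full_scale`, and `gain`.
#' @export
adc_quantize <- function(signal, config = embedded_config(),
                         signal_std = stats::sd(signal)) {
  fs_range <- config$sigma_mult * signal_std
  n_levels <- 2^config$adc_bits
  lsb <- 2 * fs_range / n_levels
  codes <- floor((signal + fs_range) / lsb)
  codes <- pmin(pmax(codes, 0), n_levels - 1)
  list(codes = as.integer(codes), lsb = lsb, full_scale = fs_range,
       gain = compute_gain(signal_std, config$adc_bits, config$vref,
                           config$sigma_mult))
}

#' Reconstruct signal values from ADC codes
#' @param codes Integer codes from [adc_quantize()].
#' @param lsb,full_scale Scaling returned by [adc_quantize()].
#' @export
adc_dequantize <- function(codes, lsb, full_scale) {
  (codes + 0.5) * lsb - full_scale
}

# per-feature integer bits for the Q-format, from the ADC width and epoch
# length; frac bits = word_bits - 1 - int_bits (sign bit reserved)
fxp_int_bits <- function(adc_bits, n_samples) {
  b <- adc_bits
  lg <- ceiling(log2(n_samples))
  c(mean = b, mad = b, variance = 2 * b, skewness = 6, kurtosis = 9,
    line_length = b + lg, autocorrelation = 1, bp_beta = 2 * b,
    bp_gamma = 2 * b, power_ratio = 8)
}

# truncate to signed fixed point: floor toward zero at 2^-frac resolution,
# saturating at the word's range; returns value plus saturation flag
fxp_trunc <- function(v, frac_bits, word_bits) {
  scale <- 2^frac_bits
  lim <- 2^(word_bits - 1) - 1
  q <- trunc(v * scale)
  sat <- abs(q) > lim
  q <- pmin(pmax(q, -lim), lim)
  list(value = q / scale, saturated = any(sat))
}

#' Fixed-point feature vector for one quantized epoch
#'
#' Recomputes the ten features from centered ADC codes with every feature
#' value truncated to a `word_bits`-wide signed fixed-point word in a
#' per-feature Q-format (integer bits sized to the feature's dynamic range
#' at the given ADC width; saturating, not wrapping). Spectral features are
#' computed with a floating FFT, as on the target's DSP accelerator, and
#' truncated at the output accumulation. Results are rescaled by the ADC
#' LSB so they are directly comparable to the floating pipeline.
#'
#' @param codes Integer ADC codes for one epoch.
#' @param fs Sampling rate in Hz.
#' @param config An [embedded_config()].
#' @param lsb ADC LSB in signal units (from [adc_quantize()]); use 1 to
#'   stay in code units.
#' @return Named 10-vector with attribute `saturations` (count of saturated
#'   feature words).
#' @export
fixed_point_features <- function(codes, fs, config = embedded_config(),
                                 lsb = 1) {
  wb <- config$word_bits
  n <- length(codes)
  ib <- fxp_int_bits(config$adc_bits, n)
  fb <- wb - 1 - ib
  # centered codes; the half-code offset removes the mid-rise bias
  cc <- codes - 2^(config$adc_bits - 1) + 0.5
  sat <- 0
  tr <- function(v, name) {
    r <- fxp_trunc(v, fb[[name]], wb)
    if (r$saturated) sat <<- sat + 1
    r$value
  }
  mu <- tr(mean(cc), "mean")
  d <- cc - mu
  m2 <- mean(d^2)
  out <- c(
    mean = mu,
    mad = tr(mean(abs(d)), "mad"),
    variance = tr(m2, "variance"),
    skewness = tr(if (m2 > 0) mean(d^3) / m2^1.5 else 0, "skewness"),
    kurtosis = tr(if (m2 > 0) mean(d^4) / m2^2 else 0, "kurtosis"),
    line_length = tr(sum(abs(diff(cc))), "line_length"),
    autocorrelation = tr(autocorrelation(cc), "autocorrelation"),
    bp_beta = tr(band_power(cc, fs, 13, 30), "bp_beta"),
    bp_gamma = tr(band_power(cc, fs, 30, 50, closed_upper = TRUE),
                  "bp_gamma"),
    power_ratio = tr(power_ratio(cc, fs), "power_ratio"))
  # rescale from code units to signal units (amplitude power per feature)
  pow <- c(1, 1, 2, 0, 0, 1, 0, 2, 2, 0)
  out <- out * lsb^pow
  names(out) <- feature_names()
  attr(out, "saturations") <- sat
  out
}

#' Run the embedded acquisition + feature path over an epoch set
#'
#' Per channel: the block signal is scaled and quantized through the
#' simulated ADC (standard deviation taken from the block itself), then
#' each epoch's features are computed in fixed point and rescaled to signal
#' units.
#'
#' @param epoch_set An `epoch_set` (causally preprocessed for full
#'   fidelity, though the simulation accepts any).
#' @param config An [embedded_config()].
#' @return A `feature_set` like [feature_matrix()]'s, plus a
#'   `saturation_count`.
#' @export
embedded_featurize <- function(epoch_set, config = embedded_config()) {
  n_ep <- dim(epoch_set$data)[1]
  nch <- dim(epoch_set$data)[2]
  spe <- dim(epoch_set$data)[3]
  feats <- array(0, c(n_ep, nch, 10L),
                 dimnames = list(NULL, NULL, feature_names()))
  sat_total <- 0
  for (ch in seq_len(nch)) {
    x <- as.numeric(t(epoch_set$data[, ch, ]))
    q <- adc_quantize(x, config)
    codes <- matrix(q$codes, nrow = spe)
    for (e in seq_len(n_ep)) {
      fv <- fixed_point_features(codes[, e], epoch_set$fs, config, q$lsb)
      feats[e, ch, ] <- fv
      sat_total <- sat_total + attr(fv, "saturations")
    }
  }
  structure(
    list(features = feats, labels = epoch_set$labels,
         artifact_mask = epoch_set$artifact_mask,
         epoch_start_s = epoch_set$epoch_start_s,
         epoch_len_s = epoch_set$epoch_len_s,
         annotations = epoch_set$annotations,
         block_id = epoch_set$block_id, fs = epoch_set$fs,
         saturation_count = sat_total),
    class = "feature_set")
}

# ---- compact forest serialization -----------------------------------------
#
# Little-endian binary layout:
#   magic   "ICFR"                     4 bytes
#   version uint8                      1 byte
#   n_trees uint16                     2 bytes
#   n_nodes uint32                     4 bytes
#   scales  10 x float64              80 bytes   (per-feature threshold LSB)
#   roots   n_trees x uint32           4 bytes each (global node offset)
# then one 5-byte record per node:
#   threshold int16  (fixed point: value = threshold * scale[feature])
#   child_or_label uint16 (internal: tree-local index of the right child;
#                          the left child always follows its parent; leaf:
#                          the class label)
#   feature uint8 (0-based feature index; 0xFF marks a leaf)

FOREST_MAGIC <- charToRaw("ICFR")
FOREST_HEADER_BYTES <- function(n_trees) 4L + 1L + 2L + 4L + 80L + 4L * n_trees

#' Serialize a forest to the compact 5-byte-per-node format
#'
#' Thresholds are quantized to 16-bit fixed point with one stored scale per
#' feature (the largest magnitude maps to the int16 range).
#'
#' @param model An `rf_model`.
#' @param scales Optional length-10 per-feature threshold scales; computed
#'   from the forest when `NULL`. An out-of-range threshold under given
#'   scales is an error.
#' @return A `serialized_forest`: list with the raw `bytes`, `scales`,
#'   `n_trees`, `n_nodes`.
#' @export
serialize_forest <- function(model, scales = NULL) {
  trees <- model$trees
  n_trees <- length(trees)
  if (is.null(scales)) {
    mx <- rep(0, 10)
    for (tr in trees) {
      int <- tr$feature >= 0
      if (any(int)) {
        for (f in unique(tr$feature[int])) {
          mx[f + 1] <- max(mx[f + 1], max(abs(tr$threshold[int & tr$feature == f])))
        }
      }
    }
    scales <- pmax(mx / 32767, 1e-300)
  }
  if (length(scales) != 10) stopf("need 10 per-feature scales")
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(FOREST_MAGIC, con)
  writeBin(as.raw(1L), con)
  writeBin(as.integer(n_trees), con, size = 2, endian = "little")
  n_nodes <- sum(vapply(trees, function(t) length(t$feature), integer(1)))
  writeBin(as.integer(n_nodes), con, size = 4, endian = "little")
  writeBin(as.double(scales), con, size = 8, endian = "little")
  roots <- cumsum(c(0L, utils::head(vapply(trees, function(t) length(t$feature),
                                           integer(1)), -1)))
  writeBin(as.integer(roots), con, size = 4, endian = "little")
  for (tr in trees) {
    for (i in seq_along(tr$feature)) {
      if (tr$feature[i] >= 0) {
        q <- round(tr$threshold[i] / scales[tr$feature[i] + 1])
        if (abs(q) > 32767) stopf("threshold out of 16-bit range under scales")
        writeBin(as.integer(q), con, size = 2, endian = "little")
        writeBin(as.integer(tr$right[i]), con, size = 2, endian = "little")
        writeBin(as.integer(tr$feature[i]), con, size = 1)
      } else {
        writeBin(0L, con, size = 2, endian = "little")
        writeBin(as.integer(tr$label[i]), con, size = 2, endian = "little")
        writeBin(255L, con, size = 1)
      }
    }
  }
  bytes <- rawConnectionValue(con)
  structure(list(bytes = bytes, scales = scales, n_trees = n_trees,
                 n_nodes = n_nodes), class = "serialized_forest")
}

#' @export
print.serialized_forest <- function(x, ...) {
  cat(sprintf("<serialized_forest> %d trees, %d nodes, %d bytes (5 x nodes + %d header)\n",
              x$n_trees, x$n_nodes, length(x$bytes),
              FOREST_HEADER_BYTES(x$n_trees)))
  invisible(x)
}

#' Payload and header sizes of a serialized forest
#' @param sf A `serialized_forest`.
#' @return List with `total`, `header`, `payload` byte counts.
#' @export
serialized_size <- function(sf) {
  header <- FOREST_HEADER_BYTES(sf$n_trees)
  list(total = length(sf$bytes), header = header,
       payload = length(sf$bytes) - header)
}

#' Deserialize a compact forest
#'
#' Rebuilds an `rf_model`-compatible tree list; thresholds carry the 16-bit
#' quantization (value = stored int16 times the per-feature scale).
#'
#' @param sf A `serialized_forest` (or its raw bytes).
#' @return An `rf_model` whose trees hold the quantized thresholds.
#' @export
deserialize_forest <- function(sf) {
  bytes <- if (inherits(sf, "serialized_forest")) sf$bytes else sf
  con <- rawConnection(bytes, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  if (!identical(magic, FOREST_MAGIC)) stopf("bad magic in serialized forest")
  readBin(con, "raw", 1)  # version
  n_trees <- readBin(con, "integer", 1, size = 2, endian = "little",
                     signed = FALSE)
  n_nodes <- readBin(con, "integer", 1, size = 4, endian = "little")
  scales <- readBin(con, "double", 10, size = 8, endian = "little")
  roots <- readBin(con, "integer", n_trees, size = 4, endian = "little")
  feature <- integer(n_nodes)
  threshold <- numeric(n_nodes)
  right <- integer(n_nodes)
  label <- integer(n_nodes)
  for (i in seq_len(n_nodes)) {
    thr_q <- readBin(con, "integer", 1, size = 2, endian = "little")
    child <- readBin(con, "integer", 1, size = 2, endian = "little",
                     signed = FALSE)
    f <- readBin(con, "integer", 1, size = 1, signed = FALSE)
    if (f == 255) {
      feature[i] <- -1L
      label[i] <- child
      right[i] <- -1L
    } else {
      feature[i] <- f
      threshold[i] <- thr_q * scales[f + 1]
      right[i] <- child
      label[i] <- -1L
    }
  }
  sizes <- diff(c(roots, n_nodes))
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    idx <- (roots[t] + 1):(roots[t] + sizes[t])
    trees[[t]] <- list(feature = feature[idx], threshold = threshold[idx],
                       right = right[idx], label = label[idx])
  }
  structure(list(trees = trees, oob_error = NA_real_, n_trees = n_trees,
                 mtry = NA_integer_, min_node = NA_integer_,
                 seed = NA_integer_, n_features = 10L,
                 feature_names = feature_names()),
            class = "rf_model")
}

#' Forest write/read convenience for the binary format
#' @param sf A `serialized_forest`.
#' @param path File path.
#' @export
write_forest_binary <- function(sf, path) {
  writeBin(sf$bytes, path)
  invisible(path)
}

#' @rdname write_forest_binary
#' @export
read_forest_binary <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  n_trees <- readBin(bytes[6:7], "integer", 1, size = 2, endian = "little",
                     signed = FALSE)
  n_nodes <- readBin(bytes[8:11], "integer", 1, size = 4, endian = "little")
  scales <- readBin(bytes[12:91], "double", 10, size = 8, endian = "little")
  structure(list(bytes = bytes, scales = scales, n_trees = n_trees,
                 n_nodes = n_nodes), class = "serialized_forest")
}

# traverse one tree of a deserialized model; returns label and visits
traverse_tree <- function(tr, x) {
  node <- 1L
  visits <- 0L
  while (tr$feature[node] >= 0) {
    visits <- visits + 1L
    node <- if (x[tr$feature[node] + 1] <= tr$threshold[node]) node + 1L
            else tr$right[node] + 1L
  }
  list(label = tr$label[node], visits = visits)
}

#' Majority vote with short-circuit early stopping
#'
#' Evaluates trees in training order; returns non-seizure as soon as
#' `stop_after_negatives` trees have voted non-seizure, or seizure as soon
#' as `n_trees - stop_after_negatives + 1` trees have voted seizure. The
#' decision always equals the full-count majority decision (ties are
#' non-seizure).
#'
#' @param forest An `rf_model` (typically from [deserialize_forest()]).
#' @param x Ten-entry feature vector.
#' @param config An [embedded_config()].
#' @return List with `decision` (0/1), `trees_evaluated`, `node_visits`.
#' @export
shortcircuit_vote <- function(forest, x, config = embedded_config()) {
  n_trees <- length(forest$trees)
  stop_neg <- config$stop_after_negatives
  need_pos <- n_trees - stop_neg + 1
  pos <- 0L
  neg <- 0L
  visits <- 0L
  for (t in seq_len(n_trees)) {
    r <- traverse_tree(forest$trees[[t]], x)
    visits <- visits + r$visits
    if (r$label == 1) pos <- pos + 1L else neg <- neg + 1L
    if (neg >= stop_neg) {
      return(list(decision = 0L, trees_evaluated = t, node_visits = visits))
    }
    if (pos >= need_pos) {
      return(list(decision = 1L, trees_evaluated = t, node_visits = visits))
    }
  }
  list(decision = as.integer(pos > n_trees / 2), trees_evaluated = n_trees,
       node_visits = visits)
}

#' Internal-node evaluations per decision over an epoch stream
#'
#' The hardware cost proxy: node visits needed per 1-s decision with
#' short-circuit voting.
#'
#' @param forest An `rf_model`.
#' @param x Feature matrix, epochs x 10.
#' @param config An [embedded_config()].
#' @return Integer vector of node visits per epoch.
#' @export
node_eval_count <- function(forest, x, config = embedded_config()) {
  x <- as.matrix(x)
  vapply(seq_len(nrow(x)), function(i) {
    shortcircuit_vote(forest, x[i, ], config)$node_visits
  }, integer(1))
}
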