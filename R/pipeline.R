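# End-to-end glue: raw recordings -> preprocessed feature blocks ->
# cross-validated detector reports.

#' Preprocess and featurize a list of recordings
#'
#' @param recordings List of `ieeg_recording`s (one seizure per block).
#' @param config A [preprocess_config()].
#' @return List of `feature_set`s, one per block.
#' @export
prepare_blocks <- function(recordings, config = preprocess_config()) {
  lapply(prepare_epochs(recordings, config), feature_matrix)
}

#' Preprocess recordings into epoch sets (without featurizing)
#'
#' @param recordings List of `ieeg_recording`s.
#' @param config A [preprocess_config()].
#' @return List of `epoch_set`s, one per block.
#' @export
prepare_epochs <- function(recordings, config = preprocess_config()) {
  lapply(seq_along(recordings), function(b) {
    preprocess_recording(recordings[[b]], config, block_id = b)
  })
}

#' Embedded-versus-float pipeline fidelity on a train/test block split
#'
#' Trains a Random Forest on one channel's float features over the training
#' blocks, then scores the test blocks twice: through the float path
#' (float features, exact thresholds) and through the embedded path (ADC
#' quantization of the test signal, fixed-point features, 16-bit quantized
#' thresholds from the serialized forest). Reports both AUCs and their
#' difference.
#'
#' @param blocks List of `feature_set`s (float features).
#' @param epoch_sets Matching list of `epoch_set`s (for re-quantization).
#' @param train_idx,test_idx Block index vectors.
#' @param channel Channel to train and score on.
#' @param seed Training seed.
#' @param emb_config An [embedded_config()].
#' @param n_trees Forest size.
#' @return List with `auc_float`, `auc_embedded`, `auc_delta`, `model`,
#'   `serialized`, and `node_evals` (per-epoch visit counts on the test
#'   blocks).
#' @export
embedded_fidelity <- function(blocks, epoch_sets, train_idx, test_idx,
                              channel = 1L, seed = 1L,
                              emb_config = embedded_config(), n_trees = 100) {
  tr <- do.call(rbind, lapply(blocks[train_idx], function(blk) {
    use <- !blk$artifact_mask[, channel]
    cbind(blk$features[use, channel, , drop = TRUE],
          as.integer(blk$labels[use]))
  }))
  model <- rf_train(tr[, 1:10], tr[, 11], n_trees = n_trees,
                    seed = derive_seed(seed, "fidelity"))
  sf <- serialize_forest(model)
  deser <- deserialize_forest(sf)
  emb_blocks <- lapply(epoch_sets[test_idx], embedded_featurize,
                       config = emb_config)
  score_blocks <- function(blks, m) {
    unlist(lapply(blks, function(blk) {
      s <- rep(NA_real_, dim(blk$features)[1])
      ok <- !blk$artifact_mask[, channel]
      s[ok] <- rf_score(m, blk$features[ok, channel, , drop = TRUE])
      s
    }))
  }
  float_scores <- score_blocks(blocks[test_idx], model)
  emb_scores <- score_blocks(emb_blocks, deser)
  labels <- unlist(lapply(blocks[test_idx], function(b) b$labels))
  auc_f <- roc_auc(float_scores, labels)$auc
  auc_e <- roc_auc(emb_scores, labels)$auc
  nev <- node_eval_count(deser, do.call(rbind, lapply(emb_blocks, function(b)
    b$features[, channel, , drop = TRUE])), emb_config)
  list(auc_float = auc_f, auc_embedded = auc_e, auc_delta = auc_f - auc_e,
       model = model, serialized = sf, node_evals = nev)
}

#' Default detection threshold per detector
#'
#' Line length: 3 z-score units; Random Forest: strict majority (0.5 vote
#' fraction); SVM: the sign of the decision value.
#' @param detector `"ll"`, `"rf"`, or `"svm"`.
#' @export
default_threshold <- function(detector) {
  switch(detector, ll = 3, rf = 0.5, svm = 0,
         stopf("unknown detector '%s'", detector))
}

#' Cross-validated evaluation of one detector on a block dataset
#'
#' Runs leave-one-seizure-block-out scoring and builds the evaluation
#' report in the requested channel mode.
#'
#' @param blocks List of `feature_set`s from [prepare_blocks()].
#' @param detector `"ll"`, `"rf"`, or `"svm"`.
#' @param mode `"single"` (best channel by AUC) or `"multi"` (max-score
#'   fusion across channels).
#' @param seed Integer seed.
#' @param threshold Detection threshold; defaults per detector.
#' @param config An [eval_config()].
#' @param ... Passed to the detector trainer via [loso_cv()].
#' @return An `eval_report`.
#' @export
run_detector <- function(blocks, detector = c("rf", "svm", "ll"),
                         mode = c("single", "multi"), seed = 1L,
                         threshold = default_threshold(detector),
                         config = eval_config(), ...) {
  detector <- match.arg(detector)
  mode <- match.arg(mode)
  scores <- loso_cv(blocks, detector, seed = seed, ...)
  eval_report(blocks, scores, threshold, mode, config)
}
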