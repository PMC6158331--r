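# Performance framework: ROC/AUC, early-detection AUC, sensitivity, false
# detections per hour, detection delay, leave-one-seizure-out CV, and
# best-channel selection.

#' Evaluation configuration
#'
#' @param early_window_s Early-detection window after onset, in seconds.
#' @param pre_onset_tolerance_s Detections this many seconds before the
#'   labeled onset count as correct with zero delay (onset-annotation
#'   inter-rater tolerance).
#' @param event_merge Merge consecutive false-positive epochs into one
#'   false-detection event.
#' @export
eval_config <- function(early_window_s = 10, pre_onset_tolerance_s = 5,
                        event_merge = TRUE) {
  if (early_window_s <= 0) stopf("early_window_s must be positive")
  if (pre_onset_tolerance_s < 0) stopf("pre_onset_tolerance_s must be >= 0")
  structure(as.list(environment()), class = "eval_config")
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores; the AUC equals the probability
#' that a random positive scores above a random negative, with ties counted
#' one half (computed by the rank formula, so it matches the trapezoid over
#' the tie-aware ROC). `NA` scores (masked epochs) are excluded.
#'
#' @param scores Numeric scores, higher = more seizure-like.
#' @param labels Logical (TRUE = positive).
#' @return List with `roc` (data frame of threshold, fpr, tpr) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.logical(labels[keep])
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stopf("AUC undefined: need both positive and negative labels")
  }
  r <- rank(scores)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  l_sorted <- labels[ord]
  tp <- cumsum(l_sorted)
  fp <- cumsum(!l_sorted)
  last <- !duplicated(s_sorted, fromLast = TRUE)
  roc <- data.frame(threshold = c(Inf, s_sorted[last]),
                    fpr = c(0, fp[last] / n_neg),
                    tpr = c(0, tp[last] / n_pos))
  list(roc = roc, auc = auc)
}

#' Relabel epochs for early-detection scoring
#'
#' Positives are ictal epochs intersecting the first `early_window_s`
#' seconds after onset; later ictal epochs are excluded from scoring
#' (returned as `NA`, neither positive nor negative); interictal epochs are
#' unchanged.
#'
#' @param labels Logical ictal labels per epoch.
#' @param epoch_start_s Epoch start times in seconds.
#' @param onset_s Seizure onset time(s) in seconds.
#' @param early_window_s Window length in seconds.
#' @param epoch_len_s Epoch length in seconds.
#' @return Logical labels with `NA` for excluded epochs.
#' @export
early_relabel <- function(labels, epoch_start_s, onset_s,
                          early_window_s = 10, epoch_len_s = 1) {
  out <- as.logical(labels)
  in_window <- rep(FALSE, length(labels))
  for (on in onset_s) {
    in_window <- in_window | (epoch_start_s < on + early_window_s &
                                epoch_start_s + epoch_len_s > on)
  }
  out[labels & !in_window] <- NA
  out
}

#' Detection delay for one seizure
#'
#' The delay is `k` seconds when the first detected ictal epoch is the k-th
#' ictal epoch (so detecting the first ictal second gives 1 s, the floor).
#' A detection in the pre-onset tolerance window counts as correct with
#' zero delay. With no detection in `[onset - tolerance, end]`, the seizure
#' is missed and `NA` is returned.
#'
#' @param detected Logical detections per epoch.
#' @param labels Logical ictal labels per epoch.
#' @param epoch_start_s Epoch start times in seconds.
#' @param onset_s Labeled onset in seconds.
#' @param tolerance_s Pre-onset tolerance in seconds.
#' @param epoch_len_s Epoch length in seconds.
#' @return Delay in seconds, or `NA` for a missed seizure.
#' @export
detection_delay <- function(detected, labels, epoch_start_s, onset_s,
                            tolerance_s = 5, epoch_len_s = 1) {
  tol_idx <- which(!labels & epoch_start_s >= onset_s - tolerance_s &
                     epoch_start_s < onset_s)
  if (any(detected[tol_idx])) return(0)
  ictal_idx <- which(labels)
  hit <- which(detected[ictal_idx])
  if (length(hit) == 0) return(NA_real_)
  hit[1] * epoch_len_s
}

#' Seizure detection sensitivity
#'
#' Fraction of seizures with at least one detection during the ictal phase
#' (including the pre-onset tolerance window), i.e. a non-missing delay.
#'
#' @param delays_s Per-seizure delays from [detection_delay()] (`NA` =
#'   missed).
#' @export
sensitivity <- function(delays_s) {
  if (length(delays_s) == 0) stopf("need at least one seizure")
  mean(!is.na(delays_s))
}

#' False detections per hour
#'
#' A false detection is a positive epoch outside the seizure and its
#' pre-onset tolerance window. With `event_merge`, consecutive false
#' epochs count as one event. The rate is normalized by the analyzed
#' non-ictal, non-masked time.
#'
#' @param detected Logical detections per epoch (masked epochs must already
#'   be `FALSE`).
#' @param labels Logical ictal labels.
#' @param epoch_start_s Epoch start times in seconds.
#' @param onset_s Seizure onset(s), for the tolerance window.
#' @param masked Logical artifact mask per epoch (excluded from analyzed
#'   time).
#' @param tolerance_s Pre-onset tolerance in seconds.
#' @param epoch_len_s Epoch length in seconds.
#' @param event_merge Merge consecutive false epochs into events.
#' @return List with `rate` (events/hour), `n_false`, `hours`.
#' @export
fdr_per_hour <- function(detected, labels, epoch_start_s, onset_s,
                         masked = NULL, tolerance_s = 5, epoch_len_s = 1,
                         event_merge = TRUE) {
  if (is.null(masked)) masked <- rep(FALSE, length(detected))
  in_tol <- rep(FALSE, length(detected))
  for (on in onset_s) {
    in_tol <- in_tol | (epoch_start_s >= on - tolerance_s &
                          epoch_start_s < on)
  }
  analyzed <- !labels & !masked
  hours <- sum(analyzed) * epoch_len_s / 3600
  if (hours <= 0) stopf("no analyzed non-ictal time")
  fp <- detected & analyzed & !in_tol
  n <- if (event_merge) {
    sum(fp & !c(FALSE, fp[-length(fp)]))  # starts of runs
  } else {
    sum(fp)
  }
  list(rate = n / hours, n_false = n, hours = hours)
}

#' Best channel by whole-seizure AUC
#'
#' @param aucs Numeric per-channel AUCs.
#' @return 1-based index of the best channel; ties go to the lowest index.
#' @export
best_channel <- function(aucs) {
  if (length(aucs) < 1) stopf("need at least one channel report")
  which.max(aucs)  # which.max returns the first maximum
}

#' Leave-one-seizure-block-out cross-validated scores
#'
#' For each one-seizure block, trains the detector per channel on all other
#' blocks (artifact-flagged epochs excluded) and scores every epoch of the
#' held-out block. The line-length detector is training-free and uses the
#' held-out block's own normalization statistics. Artifact-flagged epochs
#' receive `NA` scores (excluded from ROC, scored as non-detections).
#'
#' @param blocks List of `feature_set`s (one seizure each), from
#'   [feature_matrix()].
#' @param detector `"ll"`, `"rf"`, or `"svm"`.
#' @param seed Integer seed fanned out to per-fold training.
#' @param ... Passed to [rf_train()] / [svm_train()] (e.g. `n_trees`,
#'   grids, `max_train`).
#' @return List per block of epochs x channels score matrices.
#' @export
loso_cv <- function(blocks, detector = c("rf", "svm", "ll"), seed = 1L, ...) {
  detector <- match.arg(detector)
  if (length(blocks) < 2 && detector != "ll") {
    stopf("leave-one-block-out needs at least 2 blocks")
  }
  nch <- dim(blocks[[1]]$features)[2]
  ll_col <- which(feature_names() == "line_length")
  lapply(seq_along(blocks), function(b) {
    held <- blocks[[b]]
    n_ep <- dim(held$features)[1]
    scores <- matrix(NA_real_, n_ep, nch)
    for (ch in seq_len(nch)) {
      ok <- !held$artifact_mask[, ch]
      if (detector == "ll") {
        m <- ll_model(held$features[, ch, ll_col], mask = !ok)
        scores[ok, ch] <- ll_score(m, held$features[ok, ch, ll_col])
      } else {
        tr <- do.call(rbind, lapply(blocks[-b], function(blk) {
          use <- !blk$artifact_mask[, ch]
          cbind(blk$features[use, ch, , drop = TRUE],
                as.integer(blk$labels[use]))
        }))
        x_tr <- tr[, 1:10, drop = FALSE]
        colnames(x_tr) <- feature_names()
        y_tr <- tr[, 11]
        fold_seed <- derive_seed(seed, paste0("fold", b, "ch", ch))
        model <- if (detector == "rf") {
          rf_train(x_tr, y_tr, seed = fold_seed, ...)
        } else {
          svm_train(x_tr, y_tr, seed = fold_seed, ...)
        }
        sc_fun <- if (detector == "rf") rf_score else svm_score
        xh <- held$features[ok, ch, , drop = TRUE]
        if (sum(ok) == 1) xh <- matrix(xh, nrow = 1)
        scores[ok, ch] <- sc_fun(model, xh)
      }
    }
    scores
  })
}

#' Evaluation report for one detector
#'
#' Pools out-of-fold scores across blocks for the whole-seizure and
#' early-detection ROC/AUC, and applies the detection threshold per block
#' for sensitivity, delays, and false detections per hour.
#'
#' @param blocks List of `feature_set`s, aligned with `scores`.
#' @param scores List of per-block score matrices (epochs x channels) from
#'   [loso_cv()].
#' @param threshold Detection threshold on the score.
#' @param mode `"single"` evaluates each channel separately and reports the
#'   best channel by AUC; `"multi"` fuses channels by per-epoch maximum
#'   score before evaluation.
#' @param config An [eval_config()].
#' @return An `eval_report` list: `auc`, `auc_early`, `roc`, `sensitivity`,
#'   `fdr_per_hour`, `delays_s`, `per_channel_auc`, `channel` (single mode),
#'   `threshold`, `mode`.
#' @export
eval_report <- function(blocks, scores, threshold, mode = c("single", "multi"),
                        config = eval_config()) {
  mode <- match.arg(mode)
  nch <- ncol(scores[[1]])
  pooled_auc_ch <- function(ch) {
    s <- unlist(lapply(scores, function(m) m[, ch]))
    l <- unlist(lapply(blocks, function(b) b$labels))
    roc_auc(s, l)$auc
  }
  if (mode == "single") {
    per_ch <- vapply(seq_len(nch), pooled_auc_ch, numeric(1))
    ch <- best_channel(per_ch)
    block_scores <- lapply(scores, function(m) m[, ch])
  } else {
    per_ch <- vapply(seq_len(nch), pooled_auc_ch, numeric(1))
    ch <- NA_integer_
    block_scores <- lapply(scores, function(m) {
      apply(m, 1, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
    })
  }
  s_all <- unlist(block_scores)
  l_all <- unlist(lapply(blocks, function(b) b$labels))
  whole <- roc_auc(s_all, l_all)
  early_labels <- unlist(lapply(seq_along(blocks), function(b) {
    blk <- blocks[[b]]
    sz <- blk$annotations[blk$annotations$label == "seizure", , drop = FALSE]
    early_relabel(blk$labels, blk$epoch_start_s, sz$start_s,
                  config$early_window_s, blk$epoch_len_s)
  }))
  keep <- !is.na(early_labels)
  early <- roc_auc(s_all[keep], early_labels[keep])

  delays <- numeric(length(blocks))
  fdr_n <- 0
  fdr_hours <- 0
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    sz <- blk$annotations[blk$annotations$label == "seizure", , drop = FALSE]
    det <- !is.na(block_scores[[b]]) & block_scores[[b]] > threshold
    delays[b] <- detection_delay(det, blk$labels, blk$epoch_start_s,
                                 sz$start_s[1], config$pre_onset_tolerance_s,
                                 blk$epoch_len_s)
    masked <- apply(blk$artifact_mask, 1, all)
    f <- fdr_per_hour(det, blk$labels, blk$epoch_start_s, sz$start_s,
                      masked, config$pre_onset_tolerance_s, blk$epoch_len_s,
                      config$event_merge)
    fdr_n <- fdr_n + f$n_false
    fdr_hours <- fdr_hours + f$hours
  }
  structure(
    list(auc = whole$auc, auc_early = early$auc, roc = whole$roc,
         sensitivity = sensitivity(delays),
         fdr_per_hour = fdr_n / fdr_hours,
         delays_s = delays, per_channel_auc = per_ch, channel = ch,
         threshold = threshold, mode = mode),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> mode=%s  AUC %.3f  early AUC %.3f\n",
              x$mode, x$auc, x$auc_early))
  cat(sprintf("  sensitivity %.2f, FDR %.2f/h, mean delay %.1f s (%d/%d missed)\n",
              x$sensitivity, x$fdr_per_hour,
              mean(x$delays_s, na.rm = TRUE), sum(is.na(x$delays_s)),
              length(x$delays_s)))
  invisible(x)
}

#' Write an evaluation report to JSON
#' @param report An `eval_report`.
#' @param path Output path.
#' @export
report_to_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
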