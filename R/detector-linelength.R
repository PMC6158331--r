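# Line-length detector: z-scored line length thresholded per epoch.
# Training-free; the normalization statistics come from the block (1-h
# segment) being scored, matching clinical practice for this reference
# detector.

#' Per-block line-length normalization statistics
#'
#' Mean and standard deviation of the line-length feature over a block's
#' (non-artifact) epochs for one channel.
#'
#' @param ll Numeric vector of per-epoch line lengths for one channel.
#' @param mask Optional logical vector of artifact flags; flagged epochs are
#'   excluded from the statistics.
#' @return A `ll_model` list with `mu`, `sigma`, `threshold`.
#' @param threshold Detection threshold in z-score units.
#' @export
ll_model <- function(ll, mask = NULL, threshold = 3) {
  use <- if (is.null(mask)) rep(TRUE, length(ll)) else !mask
  mu <- mean(ll[use])
  sigma <- stats::sd(ll[use])
  if (!is.finite(sigma) || sigma <= 0) {
    stopf("degenerate block: line-length standard deviation is zero")
  }
  structure(list(mu = mu, sigma = sigma, threshold = threshold),
            class = "ll_model")
}

#' Z-scored line-length scores
#'
#' @param model A [ll_model()].
#' @param ll Numeric vector of per-epoch line lengths.
#' @return Per-epoch z-scores; detection at `z > threshold`.
#' @export
ll_score <- function(model, ll) {
  (ll - model$mu) / model$sigma
}
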