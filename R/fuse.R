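# Multichannel fusion of per-channel detector outputs.

#' Fuse per-channel detector outputs
#'
#' Binary mode is a logical OR across channels per epoch; score mode takes
#' the per-epoch maximum score, the continuous relaxation of OR (the two
#' agree pointwise once the max score is thresholded).
#'
#' @param per_channel Matrix of epochs x channels: logicals for
#'   `mode = "binary"`, numeric scores for `mode = "score"`.
#' @param mode `"binary"` or `"score"`.
#' @return Per-epoch fused vector.
#' @export
fuse_channels <- function(per_channel, mode = c("score", "binary")) {
  mode <- match.arg(mode)
  if (is.null(dim(per_channel))) per_channel <- cbind(per_channel)
  if (ncol(per_channel) < 1) stopf("need at least one channel")
  if (mode == "binary") {
    apply(per_channel, 1, any)
  } else {
    apply(per_channel, 1, max)
  }
}
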