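# The multichannel recording container and its plain-text I/O.

#' Construct an iEEG recording object
#'
#' A recording bundles a channels-by-samples signal matrix (microvolt-like
#' units) with its sampling rate, channel names, the grouping of channels
#' into physical electrodes (used for local re-referencing), and interval
#' annotations (seizures and artifacts, in seconds).
#'
#' @param signal Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one per channel.
#' @param electrode_groups Named list of channel-index vectors; the groups
#'   must partition the channel set.
#' @param annotations Data frame with columns `label` (`"seizure"` or
#'   `"artifact"`), `start_s`, `end_s`.
#' @return An object of class `ieeg_recording`.
#' @export
new_recording <- function(signal, fs, channel_names = NULL,
                          electrode_groups = NULL, annotations = NULL) {
  if (!is.matrix(signal)) signal <- matrix(signal, nrow = 1)
  nch <- nrow(signal)
  if (!is_scalar_num(fs) || fs <= 0) stopf("fs must be a positive number")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nch))
  if (is.null(electrode_groups)) electrode_groups <- list(E1 = seq_len(nch))
  if (is.null(annotations)) {
    annotations <- data.frame(label = character(0), start_s = numeric(0),
                              end_s = numeric(0))
  }
  rec <- structure(
    list(signal = signal, fs = fs, channel_names = channel_names,
         electrode_groups = electrode_groups, annotations = annotations),
    class = "ieeg_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  nch <- nrow(rec$signal)
  idx <- sort(unlist(rec$electrode_groups, use.names = FALSE))
  if (!identical(idx, seq_len(nch))) {
    stopf("electrode_groups must partition the %d channels", nch)
  }
  dur <- recording_duration(rec)
  ann <- rec$annotations
  if (nrow(ann)) {
    if (any(ann$start_s < 0 | ann$end_s > dur + 1e-9 |
            ann$end_s < ann$start_s)) {
      stopf("annotations must lie within [0, %g] s", dur)
    }
  }
  invisible(rec)
}

#' @export
print.ieeg_recording <- function(x, ...) {
  cat(sprintf("<ieeg_recording> %d channel(s), %.1f s @ %g Hz, %d annotation(s)\n",
              nrow(x$signal), recording_duration(x), x$fs, nrow(x$annotations)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An `ieeg_recording`.
#' @export
recording_duration <- function(rec) ncol(rec$signal) / rec$fs

seizure_annotations <- function(rec) {
  rec$annotations[rec$annotations$label == "seizure", , drop = FALSE]
}

add_annotation <- function(rec, label, start_s, end_s) {
  rec$annotations <- rbind(rec$annotations,
                           data.frame(label = label, start_s = start_s,
                                      end_s = end_s))
  rec
}

#' Write a recording as a plain-text bundle
#'
#' Writes `<prefix>_signal.csv` (samples in rows, one column per channel),
#' `<prefix>_annotations.csv`, and `<prefix>_meta.json` (sampling rate,
#' channel names, electrode groups).
#'
#' @param rec An `ieeg_recording`.
#' @param prefix Path prefix for the three files.
#' @return The three file paths, invisibly.
#' @export
write_recording <- function(rec, prefix) {
  sig_path <- paste0(prefix, "_signal.csv")
  ann_path <- paste0(prefix, "_annotations.csv")
  meta_path <- paste0(prefix, "_meta.json")
  sig <- as.data.frame(t(rec$signal))
  names(sig) <- rec$channel_names
  utils::write.csv(sig, sig_path, row.names = FALSE)
  utils::write.csv(rec$annotations, ann_path, row.names = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, channel_names = rec$channel_names,
         electrode_groups = rec$electrode_groups),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(sig_path, ann_path, meta_path))
}

#' Read a recording written by [write_recording()]
#' @param prefix Path prefix used when writing.
#' @return An `ieeg_recording`.
#' @export
read_recording <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  sig <- utils::read.csv(paste0(prefix, "_signal.csv"), check.names = FALSE)
  ann <- utils::read.csv(paste0(prefix, "_annotations.csv"),
                         colClasses = c("character", "numeric", "numeric"))
  groups <- lapply(meta$electrode_groups, as.integer)
  new_recording(t(as.matrix(sig)), fs = meta$fs,
                channel_names = meta$channel_names,
                electrode_groups = groups, annotations = ann)
}
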