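# Recording container: channels x time matrix with montage metadata.

#' Construct an EEG recording object
#'
#' A recording is a channels-by-time numeric matrix in microvolts plus
#' montage metadata. All package analyses start from this container.
#'
#' @param signals Numeric matrix, channels x samples, in microvolts.
#' @param labels Character vector of unique channel labels (rows of
#'   `signals`).
#' @param srate Sampling rate in Hz.
#' @param reference Reference tag: `"linked-mastoid"`, `"common-average"`
#'   or `"other"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signals, labels, srate,
                          reference = c("other", "linked-mastoid",
                                        "common-average")) {
  reference <- match.arg(reference)
  signals <- as.matrix(signals)
  if (!is.numeric(signals)) abort("`signals` must be numeric.")
  if (length(labels) != nrow(signals)) {
    abort("`labels` length must equal the number of signal rows.")
  }
  if (anyDuplicated(labels)) abort("Channel labels must be unique.")
  if (!is.numeric(srate) || length(srate) != 1 || srate <= 0) {
    abort("`srate` must be a single positive number.")
  }
  rownames(signals) <- labels
  structure(
    list(signals = signals, labels = as.character(labels),
         srate = srate, reference = reference),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), ref: %s\n",
    nrow(x$signals), ncol(x$signals), x$srate,
    ncol(x$signals) / x$srate, x$reference
  ))
  cat("channels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$signals)

rec_duration <- function(rec) ncol(rec$signals) / rec$srate

#' Re-reference a recording to the common average
#'
#' Subtracts, at every sample, the instantaneous mean across all scalp
#' channels from each channel. EOG channels (labels containing "EOG") are
#' excluded from the average and dropped from the output, since they are
#' recorded only to detect eye movements, not analyzed.
#'
#' @param rec An [eeg_recording()].
#' @return A re-referenced `eeg_recording` with `reference =
#'   "common-average"`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(c(1, 3, 3, 1), 2, byrow = TRUE),
#'                      c("F3", "F4"), srate = 1)
#' common_average_reference(rec)$signals
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  scalp <- !is_eog_label(rec$labels)
  if (sum(scalp) < 2) abort("Need at least 2 scalp channels to re-reference.")
  sig <- rec$signals[scalp, , drop = FALSE]
  avg <- colMeans(sig)
  eeg_recording(sweep(sig, 2, avg), rec$labels[scalp], rec$srate,
                reference = "common-average")
}
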