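# Epoching and threshold-based artifact rejection.

#' Construct an epoch set
#'
#' @param data Numeric array, epochs x channels x samples, microvolts.
#' @param labels Channel labels.
#' @param srate Sampling rate, Hz.
#' @param epoch_len Epoch length, seconds.
#' @param keep Logical keep-mask, one entry per epoch.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, labels, srate, epoch_len,
                       keep = rep(TRUE, dim(data)[1])) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (dim(data)[3] != round(epoch_len * srate)) {
    abort("Epoch sample count must equal epoch_len * srate exactly.")
  }
  if (length(keep) != dim(data)[1]) {
    abort("`keep` must have one entry per epoch.")
  }
  structure(
    list(data = data, labels = as.character(labels), srate = srate,
         epoch_len = epoch_len, keep = as.logical(keep)),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf(
    "<eeg_epochs> %d epochs (%d kept) x %d channels x %d samples (%g s @ %g Hz)\n",
    dim(x$data)[1], sum(x$keep), dim(x$data)[2], dim(x$data)[3],
    x$epoch_len, x$srate
  ))
  invisible(x)
}

n_kept <- function(es) sum(es$keep)

#' Cut a recording into consecutive fixed-length epochs
#'
#' The recording is segmented into consecutive, non-overlapping epochs of
#' `epoch_len` seconds; a trailing partial epoch is discarded. A 5-min
#' recording at the default 2-s epoch length yields 150 epochs, matching
#' the upper end of typical retained-epoch counts in resting-state
#' protocols. All epochs start out marked as kept.
#'
#' @param rec An [eeg_recording()].
#' @param epoch_len Epoch length in seconds (default 2, giving a 0.5 Hz
#'   spectral resolution).
#' @return An [eeg_epochs()] object.
#' @export
segment_epochs <- function(rec, epoch_len = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (epoch_len <= 0) abort("`epoch_len` must be positive.")
  spe <- round(epoch_len * rec$srate)
  n_ep <- floor(ncol(rec$signals) / spe)
  if (n_ep < 1) {
    abort("Recording shorter than one epoch; nothing to segment.",
          class = "alphamark_empty_epochs")
  }
  n_ch <- nrow(rec$signals)
  dat <- array(0, dim = c(n_ep, n_ch, spe))
  for (e in seq_len(n_ep)) {
    dat[e, , ] <- rec$signals[, ((e - 1) * spe + 1):(e * spe), drop = FALSE]
  }
  eeg_epochs(dat, rec$labels, rec$srate, epoch_len)
}

#' Reject artifactual epochs by amplitude and gradient thresholds
#'
#' An automated, reproducible stand-in for expert visual artifact
#' screening: an epoch is rejected when any channel exceeds `amp_limit`
#' in absolute amplitude or `grad_limit` in absolute sample-to-sample
#' difference. The data are never modified; rejection only clears the
#' keep-mask, and is cumulative with previous rejections.
#'
#' @param es An [eeg_epochs()] object.
#' @param amp_limit Absolute amplitude threshold, microvolts (default 100).
#' @param grad_limit Absolute gradient threshold, microvolts per sample
#'   (default 50).
#' @return The epoch set with an updated keep-mask.
#' @export
reject_artifacts <- function(es, amp_limit = 100, grad_limit = 50) {
  stopifnot(inherits(es, "eeg_epochs"))
  if (amp_limit <= 0 || grad_limit <= 0) abort("Limits must be positive.")
  keep <- es$keep
  for (e in seq_len(dim(es$data)[1])) {
    if (!keep[e]) next
    x <- es$data[e, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    amp_bad <- max(abs(x)) > amp_limit
    grad_bad <- if (ncol(x) > 1) {
      max(abs(x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE])) > grad_limit
    } else FALSE
    if (amp_bad || grad_bad) keep[e] <- FALSE
  }
  es$keep <- keep
  es
}
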