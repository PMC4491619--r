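# Magnitude-squared coherence over electrode pairs.

epoch_fft <- function(es, label, kept, w) {
  ch <- match(label, es$labels)
  if (is.na(ch)) {
    abort(paste("Channel not in montage:", label),
          class = "alphamark_montage")
  }
  seg <- matrix(aperm(es$data[kept, ch, , drop = FALSE], c(3, 1, 2)),
                nrow = dim(es$data)[3])
  mvfft(seg * w)
}

#' Magnitude-squared coherence between two channels
#'
#' Welch coherence: cross- and autospectra are averaged over the same
#' kept epochs (Hanning-windowed, consecutive 2-s segments), then
#' `|<Sxy>|^2 / (<Sxx> <Syy>)` is formed per frequency bin on the 2-45 Hz
#' grid. Values lie in `[0, 1]`: 0 is no linear coupling, 1 maximal.
#' At least two kept epochs are required -- the single-segment estimate is
#' identically 1. No bias correction is applied; the small-sample bias
#' floor for independent signals is about `1 / epochs_used`.
#'
#' @param es An [eeg_epochs()] object.
#' @param pair Character vector of two channel labels.
#' @param fmin,fmax Grid limits in Hz (defaults 2 and 45).
#' @return A tibble `freq`, `coherence` with attribute `epochs_used`.
#' @export
ms_coherence <- function(es, pair, fmin = 2, fmax = 45) {
  stopifnot(inherits(es, "eeg_epochs"), length(pair) == 2)
  kept <- which(es$keep)
  if (length(kept) < 2) {
    abort("Coherence needs at least 2 kept epochs.",
          class = "alphamark_insufficient_epochs")
  }
  n <- dim(es$data)[3]
  w <- as.numeric(signal::hanning(n))
  res <- 1 / es$epoch_len
  k <- seq(ceiling(fmin / res), floor(fmax / res))

  fx <- epoch_fft(es, pair[1], kept, w)
  fy <- epoch_fft(es, pair[2], kept, w)
  sxy <- rowMeans(fx * Conj(fy))
  sxx <- rowMeans(Mod(fx)^2)
  syy <- rowMeans(Mod(fy)^2)
  coh <- Mod(sxy)^2 / (sxx * syy)
  out <- tibble::tibble(freq = k * res, coherence = coh[k + 1])
  structure(out, epochs_used = length(kept), class = class(out))
}

#' Summarize per-bin coherence by band
#'
#' Mean coherence over the frequency bins of each band of an
#' individualized band scheme (same bin-membership rule as band powers).
#'
#' @param coh_bins A `freq`/`coherence` tibble from [ms_coherence()].
#' @param scheme A [build_band_scheme()] result.
#' @return A tibble `band`, `coherence`.
#' @export
band_coherence <- function(coh_bins, scheme) {
  stopifnot(inherits(scheme, "band_scheme"))
  vals <- purrr::pmap_dbl(
    scheme[c("lo", "hi", "hi_closed")],
    function(lo, hi, hi_closed) {
      sel <- band_bins(coh_bins$freq, lo, hi, hi_closed)
      if (!any(sel)) {
        abort(sprintf("Band [%g, %g) contains no frequency bins.", lo, hi),
              class = "alphamark_empty_band")
      }
      mean(coh_bins$coherence[sel])
    }
  )
  tibble::tibble(band = factor(scheme$band, levels = scheme$band),
                 coherence = vals)
}

#' Coherence profile over the standard electrode pairs
#'
#' Band-level coherence for the three pair sets -- left intrahemispheric,
#' right intrahemispheric, and interhemispheric (see [pair_sets()]) --
#' giving the 9 pairs x 8 bands table entering the cohort ANOVAs.
#'
#' @param es An [eeg_epochs()] object containing all nine pair labels.
#' @param scheme A [build_band_scheme()] result.
#' @param subject Optional subject identifier column.
#' @return A long tibble: `subject`, `set`, `pair`, `band`, `coherence`.
#' @export
coherence_profile <- function(es, scheme, subject = NA_character_) {
  pairs <- pair_sets()
  purrr::pmap_dfr(pairs, function(set, ch1, ch2) {
    bc <- band_coherence(ms_coherence(es, c(ch1, ch2)), scheme)
    tibble::tibble(subject = subject, set = set,
                   pair = paste0(ch1, "-", ch2),
                   band = bc$band, coherence = bc$coherence)
  })
}
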