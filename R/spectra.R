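# Welch spectra and the TF/IAF anchor frequencies.

#' Welch power spectral density over kept epochs
#'
#' Per-channel PSD computed as the average over kept epochs of
#' Hanning-windowed periodograms (no overlap: consecutive epochs are the
#' Welch segments, no phase shift). Density scaling with window-power
#' correction; the grid is restricted to 2-45 Hz at the native resolution
#' `1 / epoch_len` (0.5 Hz for 2-s epochs).
#'
#' @param es An [eeg_epochs()] object with at least one kept epoch.
#' @param fmin,fmax Frequency grid limits in Hz (default 2 and 45).
#' @return A tibble with columns `channel`, `freq` (Hz) and `power`
#'   (uV^2/Hz), carrying attributes `epochs_used`, `srate` and
#'   `resolution`; class `psd_tbl`.
#' @export
welch_psd <- function(es, fmin = 2, fmax = 45) {
  stopifnot(inherits(es, "eeg_epochs"))
  kept <- which(es$keep)
  if (length(kept) < 1) {
    abort("No kept epochs; cannot estimate a spectrum.",
          class = "alphamark_empty_input")
  }
  n <- dim(es$data)[3]
  w <- as.numeric(signal::hanning(n))
  res <- 1 / es$epoch_len
  k <- seq(ceiling(fmin / res), floor(fmax / res))
  freqs <- k * res
  denom <- es$srate * sum(w^2)

  out <- purrr::map_dfr(seq_along(es$labels), function(ch) {
    seg <- t(es$data[kept, ch, , drop = FALSE][, 1, ])   # samples x epochs
    if (length(kept) == 1) seg <- matrix(es$data[kept, ch, ], ncol = 1)
    fx <- mvfft(seg * w)
    pxx <- 2 * rowMeans(Mod(fx)^2) / denom               # one-sided density
    tibble::tibble(channel = es$labels[ch], freq = freqs,
                   power = pxx[k + 1])
  })
  structure(out, epochs_used = length(kept), srate = es$srate,
            resolution = res, class = c("psd_tbl", class(out)))
}

#' Average a multi-channel spectrum across electrodes
#'
#' Unweighted per-bin mean over all channels; anchor frequencies are
#' detected on this electrode-averaged spectrum.
#'
#' @param ps A `psd_tbl` tibble from [welch_psd()] (or any tibble with
#'   `channel`, `freq`, `power`).
#' @return A tibble with columns `freq`, `power`.
#' @export
grand_average_spectrum <- function(ps) {
  if (!all(c("freq", "power") %in% names(ps))) {
    abort("Expected columns `freq` and `power`.")
  }
  atts <- attributes(ps)[c("epochs_used", "srate", "resolution")]
  out <- ps |>
    dplyr::group_by(.data$freq) |>
    dplyr::summarise(power = mean(.data$power), .groups = "drop")
  attributes(out) <- c(attributes(out), atts[!vapply(atts, is.null, TRUE)])
  out
}

#' Detect the individual alpha frequency (IAF)
#'
#' The IAF is the frequency of the maximum power bin of the
#' electrode-averaged spectrum within the extended alpha range, 5-14 Hz.
#' Ties are broken toward the lower frequency (deterministic; ties have
#' measure zero with noisy data).
#'
#' @param avg A single-channel spectrum tibble (`freq`, `power`).
#' @param range Search range in Hz, default `c(5, 14)`.
#' @return The IAF in Hz (a value on the spectrum's frequency grid).
#' @export
detect_iaf <- function(avg, range = c(5, 14)) {
  sel <- avg$freq >= range[1] & avg$freq <= range[2]
  if (!any(sel)) abort("Spectrum grid does not cover the alpha search range.")
  f <- avg$freq[sel]; p <- avg$power[sel]
  if (all(p <= 0)) {
    abort("No power in the alpha search range; cannot locate a peak.",
          class = "alphamark_no_peak")
  }
  f[which.max(p)]    # which.max returns the first (lowest-frequency) maximum
}

#' Detect the theta/alpha transition frequency (TF)
#'
#' The TF estimates where the theta and alpha spectra intersect: the
#' frequency of minimum power in `[search_lo, iaf)` on the
#' electrode-averaged spectrum. The default floor of 3 Hz keeps the search
#' clear of the delta roll-off. Ties are broken toward the higher
#' frequency, i.e. closest to the alpha rise; when the spectrum is
#' monotone increasing on the window the boundary value `search_lo` is
#' returned.
#'
#' @param avg A single-channel spectrum tibble (`freq`, `power`).
#' @param iaf IAF in Hz (upper, exclusive, end of the search window).
#' @param search_lo Lower end of the search window in Hz (default 3).
#' @return The TF in Hz.
#' @export
detect_tf <- function(avg, iaf, search_lo = 3) {
  if (search_lo >= iaf) abort("`search_lo` must be below `iaf`.")
  sel <- avg$freq >= search_lo & avg$freq < iaf
  if (!any(sel)) {
    abort("Empty TF search window on this grid.", class = "alphamark_window")
  }
  f <- avg$freq[sel]; p <- avg$power[sel]
  idx <- which(p == min(p))
  f[idx[length(idx)]]  # tie toward the higher frequency
}

#' Normalize a spectrum to relative power
#'
#' Divides each bin by that channel's mean power over the full 2-45 Hz
#' grid, so the mean relative power per channel is exactly 1. Relative
#' band powers and band-power ratios are invariant to any overall scaling
#' of the recording.
#'
#' @param ps A `psd_tbl` tibble (or a single-channel `freq`/`power`
#'   tibble).
#' @return A tibble of the same shape with `power` replaced by relative
#'   power (dimensionless).
#' @export
relative_power <- function(ps) {
  atts <- attributes(ps)[c("epochs_used", "srate", "resolution")]
  if ("channel" %in% names(ps)) {
    means <- ps |>
      dplyr::group_by(.data$channel) |>
      dplyr::summarise(m = mean(.data$power), .groups = "drop")
    if (any(means$m <= 0)) {
      abort(paste("Zero-power channel(s):",
                  paste(means$channel[means$m <= 0], collapse = ", ")),
            class = "alphamark_degenerate_channel")
    }
    out <- ps |>
      dplyr::group_by(.data$channel) |>
      dplyr::mutate(power = .data$power / mean(.data$power)) |>
      dplyr::ungroup()
  } else {
    if (mean(ps$power) <= 0) {
      abort("Zero-power spectrum.", class = "alphamark_degenerate_channel")
    }
    out <- dplyr::mutate(ps, power = .data$power / mean(.data$power))
  }
  attributes(out) <- c(attributes(out), atts[!vapply(atts, is.null, TRUE)])
  out
}
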