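# Individually anchored band construction and relative band powers.

band_names <- c("delta", "theta", "alpha1", "alpha2", "alpha3",
                "beta1", "beta2", "gamma")

#' Build a subject-specific band scheme from the TF and IAF anchors
#'
#' Bands are anchored to the subject's transition frequency (TF) and
#' individual alpha frequency (IAF): delta `[TF-4, TF-2)`, theta
#' `[TF-2, TF)`, alpha1 `[TF, mid)` and alpha2 `[mid, IAF)` with `mid =
#' (TF+IAF)/2`, alpha3 `[IAF, IAF+2)`. The beta/gamma edges are fixed by
#' default: beta1 `[IAF+2, b1_hi)`, beta2 `[b1_hi, b2_hi)`, gamma
#' `[b2_hi, 45]` (gamma is closed at the top of the analysis grid).
#' Boundaries are kept as exact real values -- bin membership uses
#' half-open intervals, so off-grid midpoints (e.g. TF 6.5, IAF 10 ->
#' mid 8.25) never double-count a bin. A delta lower edge below the 2 Hz
#' grid floor is clipped with a warning.
#'
#' @param tf,iaf Anchor frequencies in Hz (`tf < iaf`).
#' @param b1_hi,b2_hi Fixed upper edges of beta1 and beta2 in Hz
#'   (defaults 19.2 and 32.4).
#' @param grid_lo,grid_hi Analysis grid limits in Hz (defaults 2 and 45).
#' @return A tibble of class `band_scheme` with columns `band`, `lo`,
#'   `hi`, `hi_closed`, and attributes `tf`, `iaf`.
#' @export
#' @examples
#' build_band_scheme(tf = 6.9, iaf = 10.9)
build_band_scheme <- function(tf, iaf, b1_hi = 19.2, b2_hi = 32.4,
                              grid_lo = 2, grid_hi = 45) {
  if (!is.finite(tf) || !is.finite(iaf) || iaf <= tf) {
    abort("Anchors invalid: need finite tf < iaf.",
          class = "alphamark_anchor")
  }
  if (iaf + 2 > b1_hi) abort("IAF + 2 must not exceed the beta1 upper edge.")
  mid <- (tf + iaf) / 2
  delta_lo <- tf - 4
  if (delta_lo < grid_lo) {
    warn(sprintf("Delta lower edge %.2f Hz below grid floor; clipped to %g Hz.",
                 delta_lo, grid_lo))
    delta_lo <- grid_lo
  }
  out <- tibble::tibble(
    band = band_names,
    lo = c(delta_lo, tf - 2, tf, mid, iaf, iaf + 2, b1_hi, b2_hi),
    hi = c(tf - 2, tf, mid, iaf, iaf + 2, b1_hi, b2_hi, grid_hi),
    hi_closed = c(rep(FALSE, 7), TRUE)
  )
  # clipping may leave delta empty (lo == hi); that is tolerated here and
  # surfaces as an empty-band error only if delta power is requested
  if (any(out$hi < out$lo)) abort("Band edges are not increasing.",
                                  class = "alphamark_anchor")
  structure(out, tf = tf, iaf = iaf,
            class = c("band_scheme", class(out)))
}

band_bins <- function(freqs, lo, hi, hi_closed) {
  if (hi_closed) freqs >= lo & freqs <= hi else freqs >= lo & freqs < hi
}

#' Relative band powers and the alpha3/alpha2 and theta/gamma ratios
#'
#' The relative power of a band is the mean relative power over the
#' frequency bins falling in it (half-open intervals; gamma closed at
#' 45 Hz). For multi-channel input, per-channel band means are averaged
#' across electrodes. The alpha3/alpha2 ratio -- upper alpha over the
#' upper half of low alpha -- is the stratification biomarker; the
#' theta/gamma ratio is reported alongside. Both ratios are identical
#' whether absolute or relative powers are used, since the per-channel
#' normalizer cancels.
#'
#' @param rel A relative spectrum from [relative_power()] (with or
#'   without a `channel` column).
#' @param scheme A [build_band_scheme()] result.
#' @param subject Optional subject identifier stored in the output.
#' @return A one-row tibble: `subject`, `tf`, `iaf`, one column per band,
#'   `alpha3_alpha2`, `theta_gamma`.
#' @export
band_powers <- function(rel, scheme, subject = NA_character_) {
  stopifnot(inherits(scheme, "band_scheme"))
  avg <- if ("channel" %in% names(rel)) grand_average_spectrum(rel) else rel
  vals <- purrr::pmap_dbl(
    scheme[c("lo", "hi", "hi_closed")],
    function(lo, hi, hi_closed) {
      sel <- band_bins(avg$freq, lo, hi, hi_closed)
      if (!any(sel)) {
        abort(sprintf("Band [%g, %g) contains no frequency bins.", lo, hi),
              class = "alphamark_empty_band")
      }
      mean(avg$power[sel])
    }
  )
  names(vals) <- scheme$band
  tibble::tibble(
    subject = subject,
    tf = attr(scheme, "tf"), iaf = attr(scheme, "iaf"),
    !!!as.list(vals),
    alpha3_alpha2 = vals[["alpha3"]] / vals[["alpha2"]],
    theta_gamma = vals[["theta"]] / vals[["gamma"]]
  )
}
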