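# Analytic expected spectra for the generator: used for ground-truth
# anchors and for calibrating cohort amplitudes without simulation.
#
# Each oscillator's PSD shape is |H(f)|^4 of its Butterworth band-pass
# (filtfilt applies the filter forward and backward), normalized to unit
# total power; the background is f^(-beta) with a 1 Hz knee. Welch
# estimates see this density smeared by the squared Hanning transfer
# kernel, so expected bin values are the convolution of the model density
# with that kernel, evaluated on the analysis grid.

filter_gain4 <- function(bf, freqs, srate) {
  z <- exp(-1i * 2 * pi * freqs / srate)
  hb <- outer(z, seq_along(bf$b) - 1, `^`) %*% bf$b
  ha <- outer(z, seq_along(bf$a) - 1, `^`) %*% bf$a
  Mod(hb / ha)^4
}

# squared transfer function of the Hanning window vs frequency offset,
# normalized to integrate to 1 over offsets
hanning_kernel <- function(epoch_len, srate, df = 0.05, span = 8) {
  n <- round(epoch_len * srate)
  w <- as.numeric(signal::hanning(n))
  offs <- seq(-span, span, by = df)
  tt <- (seq_len(n) - 1) / srate
  k <- vapply(offs, function(d) Mod(sum(w * exp(-2i * pi * d * tt)))^2, 0)
  list(offsets = offs, k = k / (sum(k) * df))
}

# model PSD components on a fine grid; `peak` is the unit-variance shape
# of the alpha-peak oscillator so calibration can rescale it cheaply
model_psd_fine <- function(spec, df = 0.05, fmax_fine = 50) {
  nyq <- spec$srate / 2
  f_norm <- seq(df, nyq, by = df)          # for unit-power normalization
  f_fine <- seq(df, fmax_fine, by = df)
  bands <- osc_bands(spec)
  amps <- osc_amps(spec)

  osc_shape <- function(band, order = 2) {
    if (diff(band) <= 0) return(numeric(length(f_fine)))
    bf <- band_filter(band, spec$srate, order)
    g_norm <- filter_gain4(bf, f_norm, spec$srate)
    g <- filter_gain4(bf, f_fine, spec$srate)
    g / (sum(g_norm) * df)
  }

  base <- numeric(length(f_fine))
  for (nm in c("delta", "theta", "alpha_low")) {
    if (amps[[nm]] > 0) {
      base <- base + amps[[nm]]^2 * osc_shape(bands[[nm]], osc_order(nm))
    }
  }
  if (spec$noise_scale > 0) {
    h_norm <- 1 / pmax(f_norm, 1)^spec$noise_exponent
    h <- 1 / pmax(f_fine, 1)^spec$noise_exponent
    base <- base + spec$noise_scale^2 * h / (sum(h_norm) * df)
  }
  peak <- if (diff(bands$alpha_peak) > 0) osc_shape(bands$alpha_peak)
          else numeric(length(f_fine))
  list(freqs = f_fine, base = base, peak = peak, df = df)
}

expected_bins <- function(spec, epoch_len = 2, fmin = 2, fmax = 45) {
  res <- 1 / epoch_len
  bins <- seq(ceiling(fmin / res), floor(fmax / res)) * res
  fine <- model_psd_fine(spec)
  kern <- hanning_kernel(epoch_len, spec$srate)
  sm <- function(x) {
    vapply(bins, function(fk) {
      kk <- approx(kern$offsets, kern$k, xout = fk - fine$freqs,
                   yleft = 0, yright = 0)$y
      sum(x * kk) * fine$df
    }, 0)
  }
  list(freq = bins, base = sm(fine$base), peak = sm(fine$peak))
}

#' Analytic expected Welch spectrum of a synthetic subject
#'
#' The model power density (oscillators plus 1/f background) convolved
#' with the squared Hanning window kernel and sampled on the analysis
#' grid -- the expectation of [welch_psd()] output for any channel of
#' [generate_subject()], free of estimation noise.
#'
#' @param spec A [subject_spec()].
#' @param epoch_len Epoch length used downstream, seconds (default 2).
#' @return A tibble `freq`, `power`.
#' @export
expected_spectrum <- function(spec, epoch_len = 2) {
  eb <- expected_bins(spec, epoch_len)
  amp2 <- spec$alpha3_amp^2
  tibble::tibble(freq = eb$freq, power = eb$base + amp2 * eb$peak)
}

#' Ground-truth anchors of a synthetic subject
#'
#' The generator does not set the transition frequency directly: TF is a
#' property of the spectrum (the trough between the theta and alpha
#' rises). The recorded ground truth is therefore the anchor pair
#' detected on the analytic expected spectrum with the same detectors
#' the pipeline uses.
#'
#' @param spec A [subject_spec()].
#' @param epoch_len Epoch length, seconds (default 2).
#' @return A one-row tibble `tf`, `iaf` (Hz, on the analysis grid).
#' @export
truth_anchors <- function(spec, epoch_len = 2) {
  avg <- expected_spectrum(spec, epoch_len)
  iaf <- detect_iaf(avg)
  tf <- detect_tf(avg, iaf)
  tibble::tibble(tf = tf, iaf = iaf)
}

# alpha3/alpha2 ratio implied by the expected spectrum, as a function of
# the alpha-peak amplitude; runs the same detection/band/ratio code as
# the pipeline on precomputed components
expected_ratio_fun <- function(spec, epoch_len = 2) {
  eb <- expected_bins(spec, epoch_len)
  function(alpha3_amp) {
    avg <- tibble::tibble(freq = eb$freq,
                          power = eb$base + alpha3_amp^2 * eb$peak)
    iaf <- detect_iaf(avg)
    tf <- detect_tf(avg, iaf)
    scheme <- build_band_scheme(tf, iaf)
    bp <- band_powers(relative_power(avg), scheme)
    bp$alpha3_alpha2
  }
}

# Find the alpha-peak amplitude whose expected ratio equals `target`.
# Only amplitudes at which the detected IAF is the spec's own alpha peak
# count as valid: below some amplitude the peak no longer dominates and
# the detector (rightly) snaps elsewhere, putting the ratio on a spurious
# branch. On the valid branch the ratio is monotone increasing in the
# amplitude, so a geometric scan brackets the target and bisection
# finishes the job.
calibrate_alpha3_amp <- function(spec, target, lo = 0.5, hi = 40,
                                 tol = 1e-3, epoch_len = 2) {
  eb <- expected_bins(spec, epoch_len)
  grid_iaf <- eb$freq[which.max(eb$peak)]    # the peak's own argmax bin
  valid_f <- function(a) {
    avg <- tibble::tibble(freq = eb$freq, power = eb$base + a^2 * eb$peak)
    out <- tryCatch(suppressWarnings({
      iaf <- detect_iaf(avg)
      if (iaf != grid_iaf) NA_real_
      else {
        tf <- detect_tf(avg, iaf)
        bp <- band_powers(relative_power(avg), build_band_scheme(tf, iaf))
        bp$alpha3_alpha2
      }
    }), error = function(e) NA_real_)
    out
  }
  amps <- exp(seq(log(lo), log(hi), length.out = 25))
  vals <- vapply(amps, valid_f, 0)
  ok <- which(!is.na(vals))
  if (length(ok) == 0 || target > max(vals[ok]) || target < min(vals[ok])) {
    abort(sprintf(
      "Ratio target %.3f outside achievable range [%s, %s].",
      target,
      if (length(ok)) sprintf("%.3f", min(vals[ok])) else "?",
      if (length(ok)) sprintf("%.3f", max(vals[ok])) else "?"),
      class = "alphamark_infeasible")
  }
  i_hi <- ok[which(vals[ok] >= target)[1]]
  i_lo <- max(ok[ok < i_hi], i_hi - 1)
  a_lo <- amps[max(i_lo, 1)]; a_hi <- amps[i_hi]
  for (i in 1:50) {
    mid <- (a_lo + a_hi) / 2
    fm <- valid_f(mid)
    if (!is.na(fm) && abs(fm - target) < tol) return(mid)
    if (is.na(fm) || fm < target) a_lo <- mid else a_hi <- mid
  }
  (a_lo + a_hi) / 2
}
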