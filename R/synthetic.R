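# Synthetic resting-state EEG with known spectral ground truth.
#
# A subject is a sum of band-passed white-noise oscillators over a 1/f
# background, generated independently per channel. Adjacent oscillator
# pass-bands share an edge at the theta/alpha transition, which produces a
# genuine spectral trough there (the seam of two Butterworth flanks), so
# the TF anchor is an emergent property of the spectrum rather than a free
# parameter. The dominant narrow alpha oscillator is centered on the true
# IAF. Every realization is scaled to its exact target RMS, which keeps
# band powers tight around their expected values.

#' Specify a synthetic subject
#'
#' Oscillator pass-bands (Hz): delta `[min(1.5, tf-4), tf-2]`, theta
#' `[tf-2, tf]`,
#' low alpha `[tf, iaf]` (amplitude `alpha2_amp`), and a narrow alpha
#' peak `[iaf-0.35, iaf+0.35]` (amplitude `alpha3_amp`). Amplitudes are
#' RMS values in microvolts; each channel receives independent
#' realizations. The 1/f^beta background has total RMS `noise_scale`.
#'
#' @param iaf True individual alpha frequency, Hz (in `[5, 14]`).
#' @param tf Intended theta/alpha transition, Hz (`tf < iaf`); the
#'   recorded ground-truth TF is the trough of the analytic expected
#'   spectrum, see [truth_anchors()].
#' @param delta_amp,theta_amp,alpha2_amp,alpha3_amp Oscillator RMS
#'   amplitudes, microvolts.
#' @param noise_exponent Spectral slope beta of the 1/f^beta background.
#' @param noise_scale Background RMS, microvolts.
#' @param coupling List of coupling entries, each a list with elements
#'   `pair` (two channel labels), `mix` (mixing coefficient in `[0, 1]`),
#'   and optionally `amp` (source RMS, default `theta_amp`) and `band`
#'   (source pass-band, default the theta band `[tf-2, tf]`). The first
#'   channel receives the common source with unit gain, the second with
#'   gain `mix`.
#' @param duration Recording length, seconds.
#' @param srate Sampling rate, Hz.
#' @param seed Integer seed; identical specs generate identical samples.
#' @param pure_tone If `TRUE` the alpha peak is a pure sinusoid at `iaf`
#'   (RMS `alpha3_amp`) instead of a narrow-band oscillator.
#' @return A `subject_spec` list.
#' @export
subject_spec <- function(iaf = 10.9, tf = iaf - 4,
                         delta_amp = 8, theta_amp = 5,
                         alpha2_amp = 8, alpha3_amp = 9,
                         noise_exponent = 1, noise_scale = 12,
                         coupling = list(),
                         duration = 300, srate = 250, seed = 1,
                         pure_tone = FALSE) {
  if (iaf < 5 || iaf > 14) abort("`iaf` must lie in [5, 14].",
                                 class = "alphamark_invalid_spec")
  if (tf >= iaf) abort("`tf` must be below `iaf`.",
                       class = "alphamark_invalid_spec")
  amps <- c(delta_amp, theta_amp, alpha2_amp, alpha3_amp, noise_scale)
  if (any(amps < 0)) abort("Amplitudes must be non-negative.",
                           class = "alphamark_invalid_spec")
  if (duration <= 0) abort("`duration` must be positive.",
                           class = "alphamark_invalid_spec")
  for (cp in coupling) {
    if (length(cp$pair) != 2 || is.null(cp$mix) || cp$mix < 0 || cp$mix > 1) {
      abort("Coupling entries need `pair` (2 labels) and `mix` in [0, 1].",
            class = "alphamark_invalid_spec")
    }
  }
  structure(
    list(iaf = iaf, tf = tf, delta_amp = delta_amp, theta_amp = theta_amp,
         alpha2_amp = alpha2_amp, alpha3_amp = alpha3_amp,
         noise_exponent = noise_exponent, noise_scale = noise_scale,
         coupling = coupling, duration = duration, srate = srate,
         seed = seed, pure_tone = pure_tone),
    class = "subject_spec"
  )
}

# pass-band definitions shared by the generator and the analytic spectrum
osc_bands <- function(spec) {
  list(
    # low-frequency background activity reaches below the TF search floor
    # (3 Hz) so the theta/alpha seam is the global trough of the window
    delta = c(max(0.5, min(1.5, spec$tf - 4)), spec$tf - 2),
    theta = c(spec$tf - 2, spec$tf),
    alpha_low = c(spec$tf, spec$iaf),
    alpha_peak = c(spec$iaf - 0.35, spec$iaf + 0.35)
  )
}

# the broad low-alpha filler uses a flatter (4th-order) pass-band so its
# right-edge roll-off does not open a spurious trough under a weak alpha
# peak; the narrow components stay 2nd-order
osc_order <- function(name) if (name == "alpha_low") 4 else 2

osc_amps <- function(spec) {
  c(delta = spec$delta_amp, theta = spec$theta_amp,
    alpha_low = spec$alpha2_amp, alpha_peak = spec$alpha3_amp)
}

band_filter <- function(band, srate, order = 2) {
  w <- pmin(pmax(band / (srate / 2), 1e-4), 1 - 1e-4)
  signal::butter(order, w, type = "pass")
}

scale_rms <- function(x, amp) {
  r <- sqrt(mean(x^2))
  if (r == 0) return(x * 0)
  x * (amp / r)
}

# Components are synthesized in the spectral domain: Hermitian complex
# Gaussian spectra shaped by an amplitude gain g(f), giving stationary
# Gaussian signals with PSD proportional to g(f)^2. For oscillators
# g = |H|^2 of the Butterworth band-pass -- the amplitude response of a
# zero-phase forward-backward filter -- so the analytic |H|^4 density
# used for calibration is exact. Each channel is an independent
# realization scaled (via Parseval) to exact RMS.

# Add one shaped-noise component to the accumulated spectrum `y`
# (n x nch complex, Hermitian). Noise is drawn only at the (half-spectrum)
# bins where the gain is non-negligible; the mirror bins get the
# conjugates. Columns are scaled so each channel's time-domain RMS is
# exactly `amp` (Parseval). DC and Nyquist are left at zero (all gains
# vanish there).
add_shaped_component <- function(y, gain, amp) {
  n <- nrow(y); nch <- ncol(y)
  kmax <- if (n %% 2 == 0) n / 2 else (n + 1) / 2
  half <- 2:kmax
  idx <- half[gain[half] > max(gain) * 1e-8]
  if (length(idx) == 0 || amp == 0) return(y)
  z <- matrix(complex(real = rnorm(length(idx) * nch),
                      imaginary = rnorm(length(idx) * nch)),
              length(idx), nch)
  zg <- z * gain[idx]
  ms <- 2 * colSums(Mod(zg)^2) / n^2
  zg <- sweep(zg, 2, amp / sqrt(ms), `*`)
  y[idx, ] <- y[idx, ] + zg
  y[n + 2 - idx, ] <- y[n + 2 - idx, ] + Conj(zg)
  y
}

shaped_noise_matrix <- function(n, nch, gain, amp) {
  y <- add_shaped_component(matrix(complex(real = 0), n, nch), gain, amp)
  Re(mvfft(y, inverse = TRUE)) / n
}

fft_freqs <- function(n, srate) {
  f <- (0:(n - 1)) * srate / n
  pmin(f, srate - f)
}

osc_gain <- function(band, srate, freqs, order = 2) {
  bf <- band_filter(band, srate, order)
  z <- exp(-1i * 2 * pi * freqs / srate)
  hb <- outer(z, seq_along(bf$b) - 1, `^`) %*% bf$b
  ha <- outer(z, seq_along(bf$a) - 1, `^`) %*% bf$a
  as.numeric(Mod(hb / ha)^2)
}

pink_gain <- function(beta, freqs, knee = 1) {
  g <- 1 / pmax(freqs, knee)^(beta / 2)
  g[freqs == 0] <- 0
  g
}

narrowband_osc <- function(n, srate, band, amp) {
  if (amp == 0 || diff(band) <= 0) return(numeric(n))
  g <- osc_gain(band, srate, fft_freqs(n, srate))
  drop(shaped_noise_matrix(n, 1L, g, amp))
}

pink_noise <- function(n, srate, beta, scale, knee = 1) {
  if (scale == 0) return(numeric(n))
  g <- pink_gain(beta, fft_freqs(n, srate), knee)
  drop(shaped_noise_matrix(n, 1L, g, scale))
}

#' Generate one synthetic subject
#'
#' Produces a 19-channel recording (10-20 montage, see [montage_10_20()])
#' of `spec$duration` seconds at `spec$srate` Hz. Channels are
#' independent realizations of the spec's oscillators-plus-background
#' model; coupling entries then add a shared band-limited source to the
#' named pair. Deterministic given `spec$seed`.
#'
#' @param spec A [subject_spec()].
#' @return An [eeg_recording()] with a `truth` attribute (the spec).
#' @export
generate_subject <- function(spec) {
  stopifnot(inherits(spec, "subject_spec"))
  set.seed(spec$seed)
  labels <- montage_10_20()
  nch <- length(labels)
  n <- round(spec$duration * spec$srate)
  bands <- osc_bands(spec)
  amps <- osc_amps(spec)
  freqs <- fft_freqs(n, spec$srate)

  # accumulate all components as scaled spectra, one inverse FFT at the end
  y <- matrix(complex(real = 0), n, nch)
  if (spec$noise_scale > 0) {
    y <- add_shaped_component(y, pink_gain(spec$noise_exponent, freqs),
                              spec$noise_scale)
  }
  osc_set <- c("delta", "theta", "alpha_low",
               if (!spec$pure_tone) "alpha_peak")
  for (nm in osc_set) {
    if (amps[[nm]] > 0 && diff(bands[[nm]]) > 0) {
      y <- add_shaped_component(
        y, osc_gain(bands[[nm]], spec$srate, freqs, osc_order(nm)),
        amps[[nm]])
    }
  }
  acc <- Re(mvfft(y, inverse = TRUE)) / n
  if (spec$pure_tone && amps[["alpha_peak"]] > 0) {
    t <- (seq_len(n) - 1) / spec$srate
    for (ch in seq_len(nch)) {
      phase <- runif(1, 0, 2 * pi)
      acc[, ch] <- acc[, ch] + sqrt(2) * amps[["alpha_peak"]] *
        sin(2 * pi * spec$iaf * t + phase)
    }
  }
  sig <- t(acc)
  for (cp in spec$coupling) {
    idx <- match(cp$pair, labels)
    if (anyNA(idx)) abort("Coupling pair not in montage.",
                          class = "alphamark_montage")
    amp <- cp$amp %||% spec$theta_amp
    band <- cp$band %||% bands$theta
    s <- narrowband_osc(n, spec$srate, band, amp)
    sig[idx[1], ] <- sig[idx[1], ] + s
    sig[idx[2], ] <- sig[idx[2], ] + cp$mix * s
  }
  rec <- eeg_recording(sig, labels, spec$srate)
  attr(rec, "truth") <- spec
  rec
}

#' Generate a coupled two-channel recording
#'
#' Channel 1 is `s + n1`, channel 2 is `mix * s + n2`, where `s` is a
#' band-limited common source (RMS `common_amp`) and `n1`, `n2` are
#' independent white noises (RMS `noise_amp`). The expected
#' magnitude-squared coherence at source frequencies is
#' `mix^2 Ps^2 / ((Ps + Pn) (mix^2 Ps + Pn))`: increasing in `mix` and in
#' the source-to-noise ratio, 1 when `noise_amp = 0`.
#'
#' @param common_amp Source RMS, microvolts.
#' @param mix Mixing coefficient in `[0, 1]`.
#' @param noise_amp Independent-noise RMS, microvolts.
#' @param duration Seconds.
#' @param seed Integer seed.
#' @param srate Sampling rate, Hz.
#' @param band Source pass-band, Hz.
#' @return A two-channel [eeg_recording()] (labels `ch1`, `ch2`).
#' @export
generate_coupled_pair <- function(common_amp, mix, noise_amp, duration,
                                  seed = 1, srate = 250, band = c(9, 11)) {
  if (mix < 0 || mix > 1) abort("`mix` must lie in [0, 1].",
                                class = "alphamark_invalid_spec")
  if (common_amp < 0 || noise_amp < 0 || duration <= 0) {
    abort("Amplitudes must be >= 0 and duration > 0.",
          class = "alphamark_invalid_spec")
  }
  set.seed(seed)
  n <- round(duration * srate)
  s <- narrowband_osc(n, srate, band, common_amp)
  n1 <- if (noise_amp > 0) scale_rms(rnorm(n), noise_amp) else numeric(n)
  n2 <- if (noise_amp > 0) scale_rms(rnorm(n), noise_amp) else numeric(n)
  eeg_recording(rbind(s + n1, mix * s + n2), c("ch1", "ch2"), srate)
}

#' Inject a square amplitude burst into selected epochs
#'
#' A crude artifact model used to exercise threshold-based rejection:
#' adds a constant offset of `amplitude` microvolts to `width` samples of
#' one channel in the selected epochs.
#'
#' @param es An [eeg_epochs()] object.
#' @param epochs Epoch indices to contaminate.
#' @param amplitude Burst amplitude, microvolts (default 500).
#' @param channel Channel index (default 1).
#' @param width Burst width in samples (default 25).
#' @return The modified epoch set.
#' @export
inject_burst <- function(es, epochs, amplitude = 500, channel = 1,
                         width = 25) {
  stopifnot(inherits(es, "eeg_epochs"))
  width <- min(width, dim(es$data)[3])
  for (e in epochs) {
    es$data[e, channel, seq_len(width)] <-
      es$data[e, channel, seq_len(width)] + amplitude
  }
  es
}
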