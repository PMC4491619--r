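---
title: "Individually anchored EEG bands and the alpha3/alpha2 biomarker: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individually anchored EEG bands and the alpha3/alpha2 biomarker: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(alphamark)
```

This vignette documents the models, estimators and design choices behind
the package: what is computed, under which assumptions, which knobs
matter, and what the synthetic-data tests do and do not establish about
real recordings.

## The analysis model

The pipeline operates on eyes-closed resting EEG from the 19-channel
10–20 montage sampled at 250 Hz. Preprocessing re-references to the
common average (EOG channels, if present, are excluded from the average
and dropped), cuts the recording into consecutive non-overlapping 2-s
epochs (a 5-min recording gives at most 150), and screens epochs with a
two-threshold rule — reject if any channel exceeds 100 µV in absolute
amplitude or 50 µV/sample in absolute first difference. The thresholds
are conventional peak-to-peak/gradient values for resting adult EEG and
are configuration-exposed; they are a reproducible, automated stand-in
for expert visual screening, which cannot be replicated exactly. No
additional band-pass is applied by default: acquisition filtering is
assumed done, and the synthetic generator produces in-band data. A
zero-phase equivalent filter can be enabled for real files by
preprocessing externally before ingestion.

Spectra are Welch estimates: Hanning-windowed periodograms of the 2-s
epochs, averaged over kept epochs, density-scaled with window-power
correction, on the native 0.5 Hz grid restricted to 2–45 Hz. The epochs
*are* the Welch segments (no overlap): the segmentation into consecutive
epochs fixes both the resolution (1/2 s = 0.5 Hz) and the estimator's
averaging count. Because every downstream quantity is either a ratio or
normalized per channel, the absolute PSD scaling convention cancels; the
tests therefore assert consistency against an independent
periodogram-averaging oracle rather than any particular scale.

### Anchors

The two anchors are detected on the spectrum averaged over all
electrodes:

* IAF — argmax of power in the extended alpha range 5–14 Hz. Ties break
  toward the lower frequency; with noisy data ties have measure zero,
  so the rule only pins down degenerate constructed cases.
* TF — argmin of power in `[3 Hz, IAF)`. The literature definition is
  "minimum power in the alpha range", i.e. the point where the theta
  and alpha spectra intersect; the 3 Hz floor keeps the window clear of
  the delta roll-off, and ties break toward the higher frequency
  (closest to the alpha rise). On a spectrum that only rises across the
  window the detector returns the floor — documented boundary behavior
  rather than an error, since real low-alpha-power spectra can look
  like this.

Anchors returned by the detectors always lie on the 0.5 Hz grid. Band
construction, however, accepts real-valued anchors, because group-mean
anchors (e.g. TF 6.9, IAF 10.9) are off-grid averages of on-grid
per-subject values.

### Bands, relative power, ratios

Given anchors, bands are delta `[TF−4, TF−2)`, theta `[TF−2, TF)`,
alpha1 `[TF, mid)`, alpha2 `[mid, IAF)` with `mid = (TF+IAF)/2`, alpha3
`[IAF, IAF+2)`; beta1/beta2/gamma use fixed edges 19.2 and 32.4 Hz by
default, ending at 45 Hz. The printed group-level beta/gamma edges could
be either fixed values or means of individualized edges; no construction
rule is stated for them, so the package defaults to the fixed
interpretation and exposes both edges as arguments. Boundaries stay
exact real numbers; bin membership uses half-open `[lo, hi)` intervals
(gamma closed at 45), so an off-grid midpoint such as 8.25 can never
double-count a bin. A TF below 6 would push the delta edge under the
2 Hz grid floor; it is clipped with a warning, possibly leaving delta
empty, which surfaces as an error only if delta power is actually
requested.

Relative power divides each bin by the channel's mean power over the
grid (so mean relative power is exactly 1), band power is the mean over
a band's bins, and multi-channel input is averaged across electrodes
after normalization. The alpha3/alpha2 and theta/gamma ratios are
computed from relative powers; with a shared per-channel normalizer the
ratio is algebraically identical under absolute powers, so the choice is
presentational, not substantive.

### Coherence

Magnitude-squared coherence uses the same epochs and windows as the PSD:
cross- and autospectra are averaged over the identical kept-epoch set
before the ratio is formed. The estimate is computed on common-average
referenced data, matching the power pipeline; the shared reference can
itself induce spurious low-level coupling, a known caveat of
reference-based coherence (as is volume conduction), which is why
synthetic tests characterize the estimator's bias floor explicitly —
about `1/K` for `K` averaged epochs — instead of pretending independent
channels reach zero. No bias correction is applied. Coherence needs at
least two kept epochs; a single segment gives identically 1. Band-level
coherence is the mean of per-bin coherence over the band (peak-based
summaries are a plausible alternative; the mean was chosen as the
stabler statistic).

### Cohort statistics

Stratification uses fixed ratio cutoffs 1.0 and 1.17 by default, with
half-open intervals `[0,1)`, `[1,1.17)`, `[1.17,∞)` so every ratio gets
exactly one label (the printed figures leave (1.16, 1.17) unassigned;
the half-open convention closes that gap into the middle group).
Empirical tertiles (1/3 and 2/3 type-7 quantiles) are available as an
alternative cutoff source.

The coherence ANOVA is a three-way split-plot: group between subjects,
band and pair within, run separately for left intrahemispheric, right
intrahemispheric and interhemispheric pair sets. The three-way
interaction has numerator df `(g−1)(f−1)(p−1)` — 14 for 2 groups ×
8 bands × 3 pairs — and denominator `(N−g)(f−1)(p−1)`. Sums of squares
are computed directly from cell means (verified against `aov`
error-strata output to 1e-10 in tests); Greenhouse–Geisser epsilon comes
from the pooled within-group covariance of the band × pair cells
projected onto orthonormal interaction contrasts, and the corrected
p-value is always reported next to the uncorrected one — Mauchly's W is
reported but never used to gate the correction. Post hoc comparisons
are plain pairwise contrasts; Duncan-style multiple range procedures
are deliberately not implemented (poorly specified for three-way cell
structures and statistically disfavored), and users should apply their
own multiplicity control to the pairwise output. Pearson correlations
use the exact t transform; W scores standardize a measure against an
age regression fitted on controls, `(value − (a + b·age)) / s_resid`.

## The synthetic generator

Each channel is an independent sum of Gaussian band-limited components
over a `1/f^β` background (β = 1 by default; total background RMS 12 µV):

| component  | pass-band (Hz)          | default RMS (µV) |
|------------|-------------------------|------------------|
| delta/low  | `[min(1.5, TF−4), TF−2]`| 8 |
| theta      | `[TF−2, TF]`            | 5 |
| low alpha  | `[TF, IAF]` (order 4)   | 8 |
| alpha peak | `IAF ± 0.35` (order 2)  | 9 |

Components are synthesized in the frequency domain: Hermitian complex
Gaussian spectra shaped by the amplitude response `|H(f)|²` of a
Butterworth band-pass (the zero-phase forward–backward response, so the
PSD shape is `|H|⁴`), scaled per channel to exact RMS via Parseval, and
inverse-FFT'd once per subject. This gives stationary Gaussian signals
whose expected Welch spectrum is known in closed form: the model density
convolved with the squared Hanning window kernel (`expected_spectrum()`).

Three modeling decisions deserve explanation:

* **TF is emergent, not a dial.** Two adjacent Butterworth pass-bands
  meeting at TF each contribute ~1/4 of their plateau power at the
  seam, producing a genuine spectral notch there. The recorded
  ground-truth TF is the trough the detector finds on the analytic
  expected spectrum — a spectrum property, exactly as in real data.
  The delta component extends down to 1.5 Hz because a bare 1/f valley
  between 3 Hz and the theta rise would otherwise undercut the seam
  trough, and the broad low-alpha component uses a 4th-order (flatter)
  pass-band so its right-edge roll-off cannot open a competing trough
  under a weak alpha peak. At the most extreme IAFs (12.5 Hz, where
  the theta band sits at 6.5–8.5 Hz) the delta/theta seam can still
  undercut the intended trough; this is consistent between the analytic
  truth and realizations and mirrors the behavior of trough-based TF
  pickers on real spectra with broad low-alpha activity.
* **Amplitude calibration is analytic.** For cohort generation, each
  subject's alpha-peak amplitude is found by bisection on the expected
  spectrum, running the same detectors, band construction and ratio
  code as the pipeline. No simulation is needed during calibration, and
  the exact-RMS scaling keeps realized ratios within ~1.5–2% (SD) of
  target for 5-minute recordings.
* **Defaults are chosen for comfortable anchor recovery.** The study
  this emulates reports no amplitudes or SNR. The default amplitudes
  make the alpha peak clearly dominant in 5–14 Hz, the theta bump
  visible, and the seam trough unique; they are documented choices, not
  claims about clinical recordings.

Cohort defaults mirror a 74-subject design: groups 18/38/18 with target
ratio ranges [0.77, 0.98], [1.00, 1.16], [1.17, 1.52]; true IAFs are
drawn from N(10.9, 0.5²), truncated to [9.5, 12.5] and rounded to the
0.5 Hz grid (an off-grid alpha peak splits asymmetrically across the
alpha2/alpha3 boundary and skews the achievable ratio range); per-group
covariates (age, sex, education, MMSE) match the demographics table but
carry no signal — there is deliberately no covariate–EEG dependence to
discover. Target ratios are drawn from the central 50% of each group's
range (`margin_frac = 0.25`): the Welch ratio estimate has ~1.5% SD at
150 epochs × 19 channels, so a margin of ≥ 4% of a ratio unit keeps
realized values inside their group range and clear of the fixed
cutoffs. This margin was set from that variance arithmetic, before any
recovery experiment was run.

Coupling entries add a shared band-limited source `s` to a channel pair
as `(+s, +mix·s)`; for an isolated pair the expected coherence at
source frequencies is `mix²Ps² / ((Ps+Pn)(mix²Ps+Pn))`, the standard
linear-mixing result, which the tests verify against simulation.

### What the synthetic cohort does *not* emulate

Stationary Gaussian oscillators have no amplitude bursting, no
posterior-dominant topography (all channels share one amplitude
profile), no eye-blink or muscle artifact morphology (only a square
burst injector to exercise the threshold rule), no volume conduction
beyond the common-average reference, and covariates carry no signal.
Passing tests therefore establish the *estimators* — anchor detection,
band arithmetic, ratio recovery, coherence monotonicity — under known
truth; they do not validate clinical sensitivity or specificity of the
biomarker on real recordings.

## Numerical choices and problem sizes

Degenerate inputs fail loudly with classed errors: empty epoch sets,
zero-power channels, empty bands, missing montage labels, unbalanced
ANOVA designs, infeasible cohort ratio targets (the offending group is
named). EDF I/O quantizes to 16 bits over a declared ±1000 µV physical
range (round-trip error ≤ half a step, ~0.015 µV); recordings are
written as one-second records.

Test problem sizes were picked so the full suite runs in a few minutes
on one core: 180-s subjects for the 50-seed tertile-recovery experiment
(the anchor detectors are bin-stable from ~150 s of clean data; 300-s
defaults match the emulated protocol), 20-seed mixing-monotonicity
averages on 30-s two-channel pairs, and 2×3×3-sized ANOVA oracles.
The acceptance script uses the full 300-s, 150-epoch protocol for its
spectral target.

## Known limitations

* TF detection on real spectra with weak theta activity can return the
  3 Hz search floor; inspect `plot_spectrum()` output when anchors look
  implausible.
* The Greenhouse–Geisser epsilon needs more subjects than within-cell
  contrasts (`N − g > (f−1)(p−1)`) for Mauchly's test to be defined; on
  smaller designs the statistic is reported as `NA` while epsilon is
  still computed.
* Coherence on common-average-referenced data inherits the reference's
  coupling bias; comparisons should stay within one referencing scheme.
* The EDF writer targets the plain 16-bit continuous variant only (no
  EDF+ annotations, no discontinuous records).
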