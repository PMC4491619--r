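# Cohort generation: three ratio-stratified groups with known truth.

default_ratio_targets <- function() {
  list(low = c(0.77, 0.98), middle = c(1.00, 1.16), high = c(1.17, 1.52))
}

# group-wise covariate distributions (age/education/MMSE means and SDs,
# proportion female) for a cohort stratified by the alpha3/alpha2 ratio
default_covariates <- function() {
  list(
    low = list(age = c(70.4, 7.4), education = c(8.3, 4.7),
               mmse = c(26.9, 1.2), p_female = 14 / 18),
    middle = list(age = c(68.4, 8.2), education = c(7.6, 3.7),
                  mmse = c(27.4, 1.3), p_female = 24 / 38),
    high = list(age = c(70.4, 6.7), education = c(6.6, 3.6),
                mmse = c(27.0, 1.7), p_female = 13 / 18)
  )
}

#' Specify a synthetic cohort
#'
#' Defines group sizes, the intended alpha3/alpha2 range per group,
#' covariate distributions, and the recording parameters shared by all
#' subjects. Defaults describe a 74-subject cohort split 18/38/18 into
#' low/middle/high ratio groups with ranges `[0.77, 0.98]`,
#' `[1.00, 1.16]`, `[1.17, 1.52]`. Covariates are drawn to match the
#' group demographics but carry no signal (no covariate-EEG dependence).
#'
#' @param group_sizes Named or ordered integer vector `(low, middle,
#'   high)`, each at least 1.
#' @param ratio_targets Named list of length-2 ranges, ordered and
#'   non-overlapping: `low < middle < high`.
#' @param duration,srate Recording length (s) and sampling rate (Hz).
#' @param master_seed Integer master seed; everything (subject seeds,
#'   covariates, ratio targets) derives from it.
#' @param margin_frac Targets are drawn uniformly from the central
#'   `1 - 2 * margin_frac` portion of each group's range (default 0.25),
#'   so that spectral-estimation scatter keeps realized ratios inside
#'   the range.
#' @param iaf_mean,iaf_sd Population distribution of the true IAF
#'   (normal, truncated to `[9.5, 12.5]`); defaults give a group mean
#'   near 10.9 Hz.
#' @param covariates Covariate distribution list; see
#'   `alphamark:::default_covariates()` for the structure.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(group_sizes = c(low = 18, middle = 38, high = 18),
                        ratio_targets = default_ratio_targets(),
                        duration = 300, srate = 250, master_seed = 1,
                        margin_frac = 0.25,
                        iaf_mean = 10.9, iaf_sd = 0.5,
                        covariates = default_covariates()) {
  if (length(group_sizes) != 3 || any(group_sizes < 1)) {
    abort("`group_sizes` must give three groups of at least 1 subject.",
          class = "alphamark_invalid_spec")
  }
  names(group_sizes) <- c("low", "middle", "high")
  rt <- ratio_targets[c("low", "middle", "high")]
  if (any(vapply(rt, length, 0L) != 2)) {
    abort("`ratio_targets` must have low/middle/high length-2 ranges.",
          class = "alphamark_invalid_spec")
  }
  if (!(rt$low[2] <= rt$middle[1] && rt$middle[2] <= rt$high[1])) {
    abort("Ratio targets must be ordered and non-overlapping.",
          class = "alphamark_invalid_spec")
  }
  structure(
    list(group_sizes = group_sizes, ratio_targets = rt,
         duration = duration, srate = srate, master_seed = master_seed,
         margin_frac = margin_frac, iaf_mean = iaf_mean, iaf_sd = iaf_sd,
         covariates = covariates),
    class = "cohort_spec"
  )
}

#' Generate a ratio-stratified synthetic cohort
#'
#' For every subject, a target alpha3/alpha2 ratio is drawn inside the
#' group's range and the alpha-peak amplitude is calibrated against the
#' analytic expected spectrum (same detectors and band rules as the
#' pipeline) so the realized ratio lands on target. Returns one
#' recording per subject plus a truth table with the true group, anchors
#' (from [truth_anchors()]), calibrated amplitude, covariates and seed.
#' Reproducible from `master_seed`.
#'
#' @param cspec A [cohort_spec()].
#' @param keep_recordings If `FALSE`, recordings are not returned
#'   (truth table only) -- useful when streaming subjects to disk.
#' @return A list with elements `recordings` (named list of
#'   [eeg_recording()]s) and `truth` (tibble).
#' @export
generate_cohort <- function(cspec, keep_recordings = TRUE) {
  stopifnot(inherits(cspec, "cohort_spec"))
  set.seed(cspec$master_seed)
  n_tot <- sum(cspec$group_sizes)
  seeds <- sample.int(.Machine$integer.max - 1, n_tot)

  rows <- list(); recs <- list(); i <- 0
  for (g in names(cspec$group_sizes)) {
    rng <- cspec$ratio_targets[[g]]
    pad <- cspec$margin_frac * diff(rng)
    cov <- cspec$covariates[[g]]
    for (j in seq_len(cspec$group_sizes[[g]])) {
      i <- i + 1
      target <- runif(1, rng[1] + pad, rng[2] - pad)
      # true IAFs are drawn on the analysis grid: an off-grid alpha peak
      # splits asymmetrically across the alpha2/alpha3 boundary and skews
      # the achievable ratio range
      iaf <- round(2 * pmin(pmax(rnorm(1, cspec$iaf_mean, cspec$iaf_sd),
                                 9.5), 12.5)) / 2
      age <- rnorm(1, cov$age[1], cov$age[2])
      edu <- max(3, round(rnorm(1, cov$education[1], cov$education[2])))
      mmse <- min(30, max(23, round(rnorm(1, cov$mmse[1], cov$mmse[2]))))
      sex <- if (runif(1) < cov$p_female) "F" else "M"

      base <- subject_spec(iaf = iaf, duration = cspec$duration,
                           srate = cspec$srate, seed = seeds[i])
      amp <- tryCatch(
        calibrate_alpha3_amp(base, target),
        alphamark_infeasible = function(e) {
          abort(sprintf(
            "Group '%s': ratio target %.3f infeasible (%s)",
            g, target, conditionMessage(e)),
            class = "alphamark_infeasible")
        })
      sspec <- subject_spec(iaf = iaf, alpha3_amp = amp,
                            duration = cspec$duration, srate = cspec$srate,
                            seed = seeds[i])
      id <- sprintf("S%03d", i)
      if (keep_recordings) recs[[id]] <- generate_subject(sspec)
      anch <- truth_anchors(sspec)
      rows[[i]] <- tibble::tibble(
        subject = id, group = g, target_ratio = target,
        alpha3_amp = amp, iaf_true = iaf,
        tf_anchor = anch$tf, iaf_anchor = anch$iaf,
        age = age, sex = sex, education_years = edu, mmse = mmse,
        seed = seeds[i]
      )
    }
  }
  truth <- dplyr::bind_rows(rows)
  truth$group <- factor(truth$group, levels = c("low", "middle", "high"))
  list(recordings = recs, truth = truth)
}

#' Write a cohort to disk as EDF files plus a truth table
#'
#' One EDF per subject (named `<subject>.edf`) and `truth.csv` in
#' `dir`.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_edf <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$recordings)) {
    write_edf(cohort$recordings[[id]], file.path(dir, paste0(id, ".edf")))
  }
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
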