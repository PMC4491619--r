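# Tertile stratification and cohort-level statistics.

#' Classify a subject by alpha3/alpha2 ratio
#'
#' Fixed-cutoff stratification into low/middle/high risk groups. The
#' half-open convention `[0, low_hi)` / `[low_hi, high_lo)` /
#' `[high_lo, Inf)` makes the classification total: with the default
#' printed cutoffs (1.0 and 1.17) a ratio of exactly 1.0 is middle and
#' exactly 1.17 is high, and the nominal gap (1.16, 1.17) belongs to
#' middle.
#'
#' @param ratio Non-negative alpha3/alpha2 ratio(s).
#' @param cutoffs Length-2 numeric `c(low_hi, high_lo)` with
#'   `0 < low_hi <= high_lo`, or a [derive_tertiles()] result.
#' @return Factor with levels `low`, `middle`, `high`.
#' @export
#' @examples
#' classify_tertile(c(0.9, 1.08, 1.29))
classify_tertile <- function(ratio, cutoffs = c(1.0, 1.17)) {
  cutoffs <- as.numeric(cutoffs)
  if (length(cutoffs) != 2 || cutoffs[1] <= 0 || cutoffs[1] > cutoffs[2]) {
    abort("`cutoffs` must satisfy 0 < low_hi <= high_lo.")
  }
  if (any(ratio < 0, na.rm = TRUE)) abort("Ratios must be non-negative.")
  out <- ifelse(ratio < cutoffs[1], "low",
                ifelse(ratio < cutoffs[2], "middle", "high"))
  factor(out, levels = c("low", "middle", "high"))
}

#' Empirical tertile cutoffs from a sample of ratios
#'
#' Cutoffs at the 1/3 and 2/3 quantiles (linear-interpolation quantile,
#' R type 7), giving a balanced three-way split of the sample. All-equal
#' input yields degenerate (equal) cutoffs with a warning.
#'
#' @param ratios Numeric vector, length at least 3.
#' @return Numeric `c(low_hi, high_lo)`.
#' @export
derive_tertiles <- function(ratios) {
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < 3) abort("Need at least 3 ratios.")
  q <- unname(quantile(ratios, c(1 / 3, 2 / 3), type = 7))
  if (q[1] == q[2]) {
    warn("Degenerate tertile cutoffs: sample has (nearly) constant ratios.")
  }
  q
}

# orthonormal polynomial-free contrasts (normalized Helmert)
orth_contrasts <- function(k) {
  h <- stats::contr.helmert(k)
  sweep(h, 2, sqrt(colSums(h^2)), "/")
}

#' Three-way split-plot ANOVA on coherence
#'
#' Group (between subjects) by frequency-band by electrode-pair (both
#' within subjects) ANOVA, as used to compare coherence profiles between
#' ratio-stratified groups. The statistic of interest is the three-way
#' group x band x pair interaction, with numerator df
#' `(g-1)(f-1)(p-1)` and denominator df `(N-g)(f-1)(p-1)`.
#' Greenhouse-Geisser epsilon is computed from the pooled within-group
#' covariance of the band x pair cells over the interaction contrast
#' space, and the corrected p-value is always reported alongside the
#' uncorrected one; Mauchly's sphericity statistic is reported but never
#' used to gate the correction. Group comparisons beyond the omnibus
#' tests are provided as plain pairwise contrasts (no Duncan procedure).
#'
#' @param data Long tibble with columns `subject`, `group`, `band`,
#'   `pair`, and a value column (default `coherence`). Every subject
#'   must have a complete band x pair grid.
#' @param value Name of the value column.
#' @return An object of class `alphamark_anova` with `tidy()` /
#'   `glance()` methods. Elements: `table` (all effects), `interaction`
#'   (the three-way test), `gg_epsilon`, `mauchly`.
#' @export
mixed_anova <- function(data, value = "coherence") {
  need <- c("subject", "group", "band", "pair", value)
  if (!all(need %in% names(data))) {
    abort(paste("Missing columns:",
                paste(setdiff(need, names(data)), collapse = ", ")))
  }
  d <- tibble::tibble(
    subject = factor(data$subject),
    group = factor(data$group),
    band = factor(data$band),
    pair = factor(data$pair),
    y = as.numeric(data[[value]])
  )
  f <- nlevels(d$band); p <- nlevels(d$pair); g <- nlevels(d$group)
  if (g < 2) abort("Need at least 2 groups.", class = "alphamark_design")
  counts <- table(d$subject, interaction(d$band, d$pair))
  if (any(counts != 1)) {
    abort("Unbalanced design: every subject needs every band x pair cell.",
          class = "alphamark_design")
  }
  subj_group <- d |>
    dplyr::distinct(.data$subject, .data$group)
  if (anyDuplicated(subj_group$subject)) {
    abort("Each subject must belong to exactly one group.",
          class = "alphamark_design")
  }
  n_subj <- nlevels(d$subject)

  # cell means and sums of squares for the split-plot decomposition
  gm <- mean(d$y)
  mean_of <- function(...) {
    d |>
      dplyr::group_by(...) |>
      dplyr::summarise(m = mean(.data$y), n = dplyr::n(), .groups = "drop")
  }
  ss <- function(tab) sum(tab$n * (tab$m - gm)^2)

  m_g <- mean_of(.data$group)
  m_b <- mean_of(.data$band)
  m_p <- mean_of(.data$pair)
  m_gb <- mean_of(.data$group, .data$band)
  m_gp <- mean_of(.data$group, .data$pair)
  m_bp <- mean_of(.data$band, .data$pair)
  m_gbp <- mean_of(.data$group, .data$band, .data$pair)
  m_s <- mean_of(.data$subject)
  m_sb <- mean_of(.data$subject, .data$band)
  m_sp <- mean_of(.data$subject, .data$pair)

  ss_g <- ss(m_g)
  ss_b <- ss(m_b)
  ss_p <- ss(m_p)
  ss_gb <- ss(m_gb) - ss_g - ss_b
  ss_gp <- ss(m_gp) - ss_g - ss_p
  ss_bp <- ss(m_bp) - ss_b - ss_p
  ss_gbp <- ss(m_gbp) - ss_g - ss_b - ss_p - ss_gb - ss_gp - ss_bp
  ss_s <- ss(m_s)                      # subjects (between + within group)
  ss_swg <- ss_s - ss_g                # subjects within groups
  ss_sb <- ss(m_sb) - ss_s - ss_b - (ss_gb)  # band x subject-within-group
  ss_sp <- ss(m_sp) - ss_s - ss_p - (ss_gp)
  ss_tot <- sum((d$y - gm)^2)
  ss_sbp <- ss_tot - ss_s - ss_b - ss_p - ss_gb - ss_gp - ss_bp - ss_gbp -
    ss_sb - ss_sp

  df_swg <- n_subj - g
  eff <- tibble::tibble(
    effect = c("group", "band", "group:band", "pair", "group:pair",
               "band:pair", "group:band:pair"),
    ss = c(ss_g, ss_b, ss_gb, ss_p, ss_gp, ss_bp, ss_gbp),
    df = c(g - 1, f - 1, (g - 1) * (f - 1), p - 1, (g - 1) * (p - 1),
           (f - 1) * (p - 1), (g - 1) * (f - 1) * (p - 1)),
    error_ss = c(ss_swg, ss_sb, ss_sb, ss_sp, ss_sp, ss_sbp, ss_sbp),
    error_df = c(df_swg, df_swg * (f - 1), df_swg * (f - 1),
                 df_swg * (p - 1), df_swg * (p - 1),
                 df_swg * (f - 1) * (p - 1), df_swg * (f - 1) * (p - 1))
  ) |>
    dplyr::mutate(
      F = (.data$ss / .data$df) / (.data$error_ss / .data$error_df),
      p.value = pf(.data$F, .data$df, .data$error_df, lower.tail = FALSE)
    )

  # GG epsilon and Mauchly over the band x pair interaction contrast
  # space, from the covariance of subject cell vectors pooled within group
  wide <- d |>
    dplyr::arrange(.data$pair, .data$band) |>
    tidyr::pivot_wider(id_cols = c("subject", "group"),
                       names_from = c("pair", "band"),
                       values_from = "y")
  ymat <- as.matrix(wide[, -(1:2)])
  groups <- wide$group
  k <- ncol(ymat)
  S <- matrix(0, k, k)
  for (gr in levels(groups)) {
    yg <- ymat[groups == gr, , drop = FALSE]
    if (nrow(yg) > 1) {
      cc <- sweep(yg, 2, colMeans(yg))
      S <- S + crossprod(cc)
    }
  }
  S <- S / df_swg
  M <- kronecker(orth_contrasts(p), orth_contrasts(f))  # pair x band order
  TT <- t(M) %*% S %*% M
  dint <- (f - 1) * (p - 1)
  gg_eps <- sum(diag(TT))^2 / (dint * sum(TT^2))
  eig_ok <- all(is.finite(TT))
  mauchly_w <- det(TT) / (sum(diag(TT)) / dint)^dint
  mauchly <- list(W = mauchly_w, statistic = NA_real_, df = NA_real_,
                  p.value = NA_real_)
  if (eig_ok && mauchly_w > 0 && df_swg > dint) {
    cf <- 1 - (2 * dint^2 + dint + 2) / (6 * dint * df_swg)
    chi <- -df_swg * cf * log(mauchly_w)
    dfm <- dint * (dint + 1) / 2 - 1
    mauchly <- list(W = mauchly_w, statistic = chi, df = dfm,
                    p.value = pchisq(chi, dfm, lower.tail = FALSE))
  }

  int <- eff[eff$effect == "group:band:pair", ]
  interaction <- list(
    F = int$F, df_num = int$df, df_den = int$error_df, p = int$p.value,
    gg_epsilon = gg_eps,
    gg_p = pf(int$F, gg_eps * int$df, gg_eps * int$error_df,
              lower.tail = FALSE)
  )
  structure(
    list(table = eff, interaction = interaction, gg_epsilon = gg_eps,
         mauchly = mauchly, levels = c(groups = g, bands = f, pairs = p),
         n_subjects = n_subj),
    class = "alphamark_anova"
  )
}

#' @export
print.alphamark_anova <- function(x, ...) {
  it <- x$interaction
  cat(sprintf(
    "Split-plot ANOVA (%d groups x %d bands x %d pairs, %d subjects)\n",
    x$levels[1], x$levels[2], x$levels[3], x$n_subjects))
  cat(sprintf("group x band x pair: F(%d, %d) = %.3f, p = %.4g\n",
              it$df_num, it$df_den, it$F, it$p))
  cat(sprintf("  Greenhouse-Geisser: epsilon = %.3f, corrected p = %.4g\n",
              it$gg_epsilon, it$gg_p))
  cat(sprintf("  Mauchly: W = %.4g, p = %.4g\n",
              x$mauchly$W, x$mauchly$p.value))
  invisible(x)
}

#' @rdname mixed_anova
#' @param x An `alphamark_anova` object.
#' @param ... Unused.
#' @export
tidy.alphamark_anova <- function(x, ...) {
  dplyr::rename(x$table, sumsq = "ss", statistic = "F")
}

#' @rdname mixed_anova
#' @export
glance.alphamark_anova <- function(x, ...) {
  it <- x$interaction
  tibble::tibble(
    F_interaction = it$F, df_num = it$df_num, df_den = it$df_den,
    p_uncorrected = it$p, gg_epsilon = it$gg_epsilon, gg_p = it$gg_p,
    mauchly_W = x$mauchly$W, mauchly_p = x$mauchly$p.value,
    n_subjects = x$n_subjects
  )
}

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y Numeric vectors of equal length, n >= 3, finite, with
#'   positive variance.
#' @return A tibble `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) abort("Need at least 3 finite pairs.")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    abort("Correlation undefined for zero-variance input.",
          class = "alphamark_degenerate")
  }
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Fit an age-regression norm on controls
#'
#' Regresses a measure on age in a control sample; used to express
#' patient values as age-corrected W scores.
#'
#' @param values Control measurements.
#' @param ages Control ages (variance must be positive; n >= 3).
#' @return A `control_norm` list: `intercept`, `slope`, `resid_sd`.
#' @export
fit_control_norm <- function(values, ages) {
  ok <- is.finite(values) & is.finite(ages)
  if (sum(ok) < 3 || var(ages[ok]) == 0) {
    abort("Norm needs >= 3 controls with age variance.",
          class = "alphamark_norm")
  }
  fit <- lm(values[ok] ~ ages[ok])
  rsd <- sqrt(sum(fit$residuals^2) / fit$df.residual)
  if (!is.finite(rsd) || rsd <= 0) {
    abort("Degenerate norm: zero residual variance.",
          class = "alphamark_norm")
  }
  structure(list(intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2]), resid_sd = rsd),
            class = "control_norm")
}

#' Age-corrected W score
#'
#' `(value - (intercept + slope * age)) / resid_sd` against a control
#' norm: the number of control residual SDs a measurement lies from its
#' age-predicted value.
#'
#' @param value Measurement(s).
#' @param age Age(s), years.
#' @param norm A [fit_control_norm()] result.
#' @return Numeric W score(s).
#' @export
w_score <- function(value, age, norm) {
  if (!inherits(norm, "control_norm")) abort("`norm` must be a control_norm.")
  (value - (norm$intercept + norm$slope * age)) / norm$resid_sd
}

#' Per-group cohort summary
#'
#' Mean, SD and range of the continuous covariates and of the
#' alpha3/alpha2 ratio per group, plus subject and female counts --
#' the standard demographics table of a stratified cohort. Single-subject
#' groups report SD 0 with `sd_degenerate = TRUE`.
#'
#' @param records Tibble with columns `group`, `alpha3_alpha2`, and
#'   optionally `age`, `education_years`, `mmse`, `sex`.
#' @return A tibble, one row per group x variable.
#' @export
group_summary <- function(records) {
  if (!all(c("group", "alpha3_alpha2") %in% names(records))) {
    abort("Need `group` and `alpha3_alpha2` columns.")
  }
  if (nrow(records) == 0) {
    abort("No records to summarize.", class = "alphamark_summary")
  }
  if (is.factor(records$group)) records$group <- droplevels(records$group)
  vars <- intersect(c("age", "education_years", "mmse", "alpha3_alpha2"),
                    names(records))
  long <- records |>
    dplyr::select(dplyr::all_of(c("group", vars)),
                  dplyr::any_of("sex")) |>
    tidyr::pivot_longer(dplyr::all_of(vars), names_to = "variable")
  out <- long |>
    dplyr::group_by(.data$group, .data$variable) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = ifelse(dplyr::n() > 1, sd(.data$value), 0),
      min = min(.data$value), max = max(.data$value),
      sd_degenerate = dplyr::n() < 2,
      n_female = if ("sex" %in% names(long)) sum(.data$sex == "F")
                 else NA_integer_,
      .groups = "drop"
    )
  out
}
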