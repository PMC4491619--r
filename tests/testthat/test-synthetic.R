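test_that("generation is deterministic and shapes are correct", {
  sp <- subject_spec(seed = 5, duration = 8)
  r1 <- generate_subject(sp)
  r2 <- generate_subject(sp)
  expect_identical(r1$signals, r2$signals)
  expect_equal(dim(r1$signals), c(19, 8 * 250))
  expect_equal(r1$labels, montage_10_20())
  # a different seed gives different samples
  r3 <- generate_subject(subject_spec(seed = 6, duration = 8))
  expect_false(identical(r1$signals, r3$signals))
})

test_that("a null spec produces an all-zero recording of correct shape", {
  sp <- subject_spec(delta_amp = 0, theta_amp = 0, alpha2_amp = 0,
                     alpha3_amp = 0, noise_scale = 0, duration = 3,
                     seed = 1)
  rec <- generate_subject(sp)
  expect_equal(dim(rec$signals), c(19, 750))
  expect_true(all(rec$signals == 0))
})

test_that("invalid subject specs are rejected", {
  expect_error(subject_spec(duration = 0), class = "alphamark_invalid_spec")
  expect_error(subject_spec(theta_amp = -1), class = "alphamark_invalid_spec")
  expect_error(subject_spec(iaf = 4), class = "alphamark_invalid_spec")
  expect_error(subject_spec(iaf = 10, tf = 11),
               class = "alphamark_invalid_spec")
  expect_error(subject_spec(coupling = list(list(pair = c("T3", "T4"),
                                                 mix = 1.2))),
               class = "alphamark_invalid_spec")
  expect_error(generate_coupled_pair(1, mix = -0.1, 1, 10),
               class = "alphamark_invalid_spec")
})

test_that("oscillator RMS amplitudes are exact per channel", {
  sp <- subject_spec(seed = 2, duration = 8, delta_amp = 0, theta_amp = 0,
                     alpha2_amp = 0, alpha3_amp = 0, noise_scale = 9)
  rec <- generate_subject(sp)
  rms <- sqrt(rowMeans(rec$signals^2))
  expect_equal(unname(rms), rep(9, 19), tolerance = 1e-12)
})

test_that("a pure-tone subject peaks exactly at its IAF", {
  sp <- subject_spec(iaf = 10, delta_amp = 0, theta_amp = 0,
                     alpha2_amp = 0, alpha3_amp = 1, noise_scale = 0,
                     duration = 8, seed = 3, pure_tone = TRUE)
  rec <- generate_subject(sp)
  avg <- grand_average_spectrum(welch_psd(segment_epochs(rec)))
  expect_equal(avg$freq[which.max(avg$power)], 10)
})

test_that("noiseless anchors equal the analytic ground truth on the grid", {
  for (iafv in c(9.5, 10.5, 11.5)) {
    sp <- subject_spec(iaf = iafv, noise_scale = 0.5, duration = 90,
                       seed = 7)
    anch <- truth_anchors(sp)
    rec <- generate_subject(sp)
    avg <- grand_average_spectrum(welch_psd(segment_epochs(
      common_average_reference(rec))))
    iaf_det <- detect_iaf(avg)
    tf_det <- detect_tf(avg, iaf_det)
    expect_equal(iaf_det, anch$iaf)
    expect_equal(iaf_det, iafv)
    expect_equal(tf_det, anch$tf)
  }
})

test_that("the analytic expected spectrum matches realized Welch estimates", {
  sp <- subject_spec(seed = 19, duration = 300)
  rec <- generate_subject(sp)
  ps <- welch_psd(segment_epochs(rec))
  avg <- grand_average_spectrum(ps)
  exp_sp <- expected_spectrum(sp)
  # per-bin agreement: 150 epochs x 19 channels leaves ~2% scatter
  rel_err <- abs(avg$power - exp_sp$power) / exp_sp$power
  expect_lt(median(rel_err), 0.05)
  expect_lt(max(rel_err), 0.25)
  # band-level agreement within 3%
  sch <- build_band_scheme(6.9, 10.9)
  bp_real <- band_powers(relative_power(avg), sch)
  bp_exp <- band_powers(relative_power(exp_sp), sch)
  for (b in alphamark:::band_names) {
    expect_equal(bp_real[[b]], bp_exp[[b]], tolerance = 0.03)
  }
})

test_that("cohort generation respects group sizes, targets and determinism", {
  cs <- cohort_spec(group_sizes = c(2, 2, 2), duration = 20,
                    master_seed = 3)
  sim <- suppressWarnings(generate_cohort(cs))
  expect_equal(length(sim$recordings), 6)
  expect_equal(as.integer(table(sim$truth$group)), c(2, 2, 2))
  rt <- cs$ratio_targets
  for (g in names(rt)) {
    tg <- sim$truth$target_ratio[sim$truth$group == g]
    expect_true(all(tg >= rt[[g]][1] & tg <= rt[[g]][2]))
  }
  # bit-identical rerun
  sim2 <- suppressWarnings(generate_cohort(cs))
  expect_identical(sim$truth, sim2$truth)
  expect_identical(sim$recordings[["S001"]]$signals,
                   sim2$recordings[["S001"]]$signals)
})

test_that("infeasible ratio targets fail with the offending group named", {
  cs <- cohort_spec(group_sizes = c(1, 1, 1),
                    ratio_targets = list(low = c(0.01, 0.02),
                                         middle = c(1, 1.16),
                                         high = c(1.17, 1.52)),
                    duration = 10, master_seed = 1)
  expect_error(suppressWarnings(generate_cohort(cs)), "low",
               class = "alphamark_infeasible")
})

test_that("cohort ratio targets are ordered low < middle < high", {
  expect_error(cohort_spec(ratio_targets = list(low = c(0.9, 1.1),
                                                middle = c(1.0, 1.16),
                                                high = c(1.17, 1.5))),
               class = "alphamark_invalid_spec")
  cs <- suppressWarnings(cohort_spec(group_sizes = c(1, 1, 1),
                                     duration = 15, master_seed = 9))
  sim <- suppressWarnings(generate_cohort(cs))
  m <- tapply(sim$truth$target_ratio, sim$truth$group, mean)
  expect_true(m[["low"]] < m[["middle"]] && m[["middle"]] < m[["high"]])
})
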