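test_that("Welch grid spacing equals the inverse epoch length", {
  es <- white_epochs(n_epochs = 4, epoch_len = 2)
  ps <- welch_psd(es)
  expect_equal(unique(diff(sort(unique(ps$freq)))), 0.5)
  expect_equal(range(ps$freq), c(2, 45))
  expect_equal(attr(ps, "epochs_used"), 4)
  # 1-s epochs give a 1 Hz grid
  es1 <- white_epochs(n_epochs = 4, epoch_len = 1)
  expect_equal(unique(diff(sort(unique(welch_psd(es1)$freq)))), 1)
})

test_that("a pure 10 Hz tone has its spectral argmax at 10 Hz", {
  t <- (0:(250 * 8 - 1)) / 250
  mat <- rbind(sin(2 * pi * 10 * t), sin(2 * pi * 10 * t + 1))
  ps <- welch_psd(toy_epochs(mat))
  avg <- grand_average_spectrum(ps)
  expect_equal(avg$freq[which.max(avg$power)], 10)
})

test_that("Welch PSD agrees with a direct periodogram-averaging oracle", {
  es <- white_epochs(n_epochs = 12, n_ch = 3, seed = 8, sd = 7)
  ps <- welch_psd(es)
  orc <- oracle_welch(es)
  for (ch in seq_along(es$labels)) {
    mine <- ps$power[ps$channel == es$labels[ch]]
    expect_equal(mine, unname(orc$power[ch, ]), tolerance = 1e-10)
  }
  # white noise of variance sigma^2 has density ~ sigma^2 / (srate / 2)
  flat <- mean(ps$power)
  expect_equal(flat, 49 / 125, tolerance = 0.15)
})

test_that("welch_psd refuses an empty keep mask", {
  es <- white_epochs(n_epochs = 3)
  es$keep[] <- FALSE
  expect_error(welch_psd(es), class = "alphamark_empty_input")
})

test_that("grand average is the unweighted per-bin channel mean", {
  es <- white_epochs(n_epochs = 5, n_ch = 4, seed = 3)
  ps <- welch_psd(es)
  avg <- grand_average_spectrum(ps)
  wide <- tidyr::pivot_wider(ps, names_from = "channel",
                             values_from = "power")
  expect_equal(avg$power, rowMeans(as.matrix(wide[, -1])))
  # identical channels average to any one of them
  mat <- matrix(rep(rnorm(1000), 3), 3, byrow = TRUE)
  ps2 <- welch_psd(toy_epochs(mat))
  avg2 <- grand_average_spectrum(ps2)
  expect_equal(avg2$power, ps2$power[ps2$channel == "ch1"])
})

test_that("IAF detection finds the extended-alpha argmax with low tie-break", {
  spike <- toy_avg_spectrum(function(f) ifelse(f == 10, 5, 1))
  expect_equal(detect_iaf(spike), 10)
  # Gaussian bump at 11.5 over a 1/f floor, versus exhaustive argmax
  bump <- toy_avg_spectrum(function(f) 1 / f + 3 * exp(-(f - 11.5)^2 / 0.5))
  expect_equal(detect_iaf(bump), 11.5)
  sel <- bump$freq >= 5 & bump$freq <= 14
  expect_equal(detect_iaf(bump), bump$freq[sel][which.max(bump$power[sel])])
  # exact tie resolves to the lower frequency
  tie <- toy_avg_spectrum(function(f) ifelse(f %in% c(9, 12), 7, 1))
  expect_equal(detect_iaf(tie), 9)
  # all-zero alpha range is an error
  zero <- toy_avg_spectrum(function(f) ifelse(f > 4 & f < 15, 0, 1))
  expect_error(detect_iaf(zero), class = "alphamark_no_peak")
})

test_that("TF detection finds the pre-alpha trough with high tie-break", {
  # V-shaped valley centered at 6.5 between theta and alpha bumps
  trough <- toy_avg_spectrum(function(f)
    1 + 0.3 * abs(f - 6.5) + 5 * exp(-(f - 10.5)^2 / 0.5))
  tf <- detect_tf(trough, iaf = 10.5)
  sel <- trough$freq >= 3 & trough$freq < 10.5
  expect_equal(tf, 6.5)
  expect_equal(tf, trough$freq[sel][which.min(trough$power[sel])])
  # monotone increasing spectrum returns the search floor
  mono <- toy_avg_spectrum(function(f) f)
  expect_equal(detect_tf(mono, iaf = 10), 3)
  # ties resolve toward the alpha rise
  tie <- toy_avg_spectrum(function(f) ifelse(f %in% c(4, 7), 0.1, 1))
  expect_equal(detect_tf(tie, iaf = 10), 7)
  expect_error(detect_tf(mono, iaf = 3.4, search_lo = 3.1),
               class = "alphamark_window")
})

test_that("relative power normalizes each channel to unit mean", {
  flat <- toy_avg_spectrum(function(f) rep(3.7, length(f)))
  expect_true(all(relative_power(flat)$power == 1))
  toy <- tibble::tibble(freq = 1:4, power = c(1, 2, 3, 2))
  expect_equal(relative_power(toy)$power, c(0.5, 1, 1.5, 1))
  # normalization identity on arbitrary multi-channel spectra
  ps <- welch_psd(white_epochs(n_epochs = 6, n_ch = 3, seed = 5))
  rel <- relative_power(ps)
  means <- tapply(rel$power, rel$channel, mean)
  expect_equal(as.numeric(means), rep(1, 3))
  # zero-power channel errors
  dead <- tibble::tibble(channel = "x", freq = 1:3, power = rep(0, 3))
  expect_error(relative_power(dead), class = "alphamark_degenerate_channel")
})

test_that("relative powers and ratios are invariant to recording scale", {
  sp <- subject_spec(seed = 31, duration = 12)
  rec <- generate_subject(sp)
  rec2 <- rec
  rec2$signals <- rec2$signals * 37.5
  scheme <- build_band_scheme(6.9, 10.9)
  bp1 <- band_powers(relative_power(welch_psd(segment_epochs(rec))), scheme)
  bp2 <- band_powers(relative_power(welch_psd(segment_epochs(rec2))), scheme)
  expect_equal(bp1[-1], bp2[-1], tolerance = 1e-12)
})
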