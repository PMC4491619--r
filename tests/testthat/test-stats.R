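test_that("fixed-cutoff classification matches the printed group figures", {
  expect_equal(as.character(classify_tertile(c(0.9, 1.08, 1.29))),
               c("low", "middle", "high"))
  # boundary convention: half-open intervals close the printed gap
  expect_equal(as.character(classify_tertile(c(1.0, 1.165, 1.17))),
               c("middle", "middle", "high"))
  expect_error(classify_tertile(-0.1))
  # totality: every finite non-negative ratio gets exactly one label
  set.seed(1)
  r <- runif(200, 0, 3)
  lab <- classify_tertile(r)
  expect_false(anyNA(lab))
})

test_that("empirical tertiles balance the sample", {
  cuts <- derive_tertiles(1:9)
  counts <- table(classify_tertile(1:9, cuts))
  expect_equal(as.integer(counts), c(3, 3, 3))
  # a cohort-sized sample splits within one subject of 25/25/24
  set.seed(7)
  ratios <- c(rnorm(18, 0.9, 0.05), rnorm(38, 1.08, 0.04),
              rnorm(18, 1.29, 0.08))
  cuts2 <- derive_tertiles(ratios)
  expect_equal(cuts2, unname(quantile(ratios, c(1 / 3, 2 / 3))))
  counts2 <- sort(as.integer(table(classify_tertile(ratios, cuts2))))
  expect_true(all(abs(counts2 - c(24, 25, 25)) <= 1))
  expect_warning(derive_tertiles(c(1, 1, 1, 1)), "Degenerate")
})

test_that("split-plot ANOVA agrees with the aov error-strata oracle", {
  cases <- list(c(2, 3, 2, 4), c(3, 3, 3, 3), c(2, 2, 2, 6))
  for (cs in cases) {
    d <- make_anova_data(cs[1], cs[2], cs[3], cs[4],
                         seed = sum(cs), effect = 0.1)
    fit <- mixed_anova(d, value = "y")
    orc <- summary(stats::aov(
      y ~ group * band * pair + Error(subject / (band * pair)),
      data = transform(d, subject = factor(subject), group = factor(group),
                       band = factor(band), pair = factor(pair))))
    otab <- orc[["Error: subject:band:pair"]][[1]]
    expect_equal(fit$interaction$F, otab["group:band:pair", "F value"],
                 tolerance = 1e-10)
    expect_equal(fit$interaction$p, otab["group:band:pair", "Pr(>F)"],
                 tolerance = 1e-10)
    expect_equal(fit$interaction$df_num,
                 (cs[1] - 1) * (cs[2] - 1) * (cs[3] - 1))
    # every effect F matches its stratum
    tt <- tidy(fit)
    s1 <- orc[["Error: subject"]][[1]]
    expect_equal(tt$statistic[tt$effect == "group"],
                 s1["group", "F value"], tolerance = 1e-10)
    s2 <- orc[["Error: subject:band"]][[1]]
    expect_equal(tt$statistic[tt$effect == "group:band"],
                 s2["group:band", "F value"], tolerance = 1e-10)
  }
})

test_that("ANOVA statistic shape matches a 2 x 8 x 3 design and nulls out for clones", {
  d <- make_anova_data(2, 8, 3, 5, seed = 99, effect = 0.05)
  fit <- mixed_anova(d, value = "y")
  expect_equal(fit$interaction$df_num, 14)
  expect_equal(fit$interaction$df_den, (10 - 2) * 7 * 2)
  expect_true(fit$gg_epsilon > 1 / 14 && fit$gg_epsilon <= 1 + 1e-10)
  expect_true(is.finite(fit$mauchly$W))
  gl <- glance(fit)
  expect_true(gl$gg_p >= gl$p_uncorrected - 1e-12)
  # cloning one group's data into the other removes all group effects
  d1 <- make_anova_data(1, 4, 2, 4, seed = 5)
  d2 <- d1
  d2$group <- "g2"
  d2$subject <- paste0(d1$subject, "x")
  fit0 <- mixed_anova(dplyr::bind_rows(d1, d2), value = "y")
  expect_equal(fit0$interaction$F, 0, tolerance = 1e-20)
})

test_that("ANOVA rejects unbalanced or degenerate designs", {
  d <- make_anova_data(2, 3, 2, 3, seed = 2)
  expect_error(mixed_anova(d[-1, ], value = "y"),
               class = "alphamark_design")
  d1 <- make_anova_data(1, 3, 2, 3, seed = 2)
  expect_error(mixed_anova(d1, value = "y"), class = "alphamark_design")
})

test_that("pearson_r matches exact cases and the sampling interval", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.4, 7.1)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -2 * x + 5)$r, -1)
  expect_error(pearson_r(x, rep(2, 6)), class = "alphamark_degenerate")
  expect_error(pearson_r(1:2, 2:3))
  # n = 13 bivariate normal with rho = 0.7: estimate falls inside the
  # central 95% interval computed by a brute-force oracle
  set.seed(34)
  z <- rnorm(13); e <- rnorm(13)
  y <- 0.7 * z + sqrt(1 - 0.49) * e
  r_obs <- pearson_r(z, y)$r
  set.seed(101)
  sims <- replicate(2000, {
    a <- rnorm(13); b <- 0.7 * a + sqrt(1 - 0.49) * rnorm(13)
    cor(a, b)
  })
  ci <- quantile(sims, c(0.025, 0.975))
  expect_true(r_obs >= ci[1] && r_obs <= ci[2])
})

test_that("W scores standardize against the control age regression", {
  set.seed(17)
  ages <- runif(17, 60, 80)
  vals <- 2.5 - 0.03 * ages + rnorm(17, sd = 0.1)
  norm <- fit_control_norm(vals, ages)
  # closed-form least squares oracle
  b <- cov(ages, vals) / var(ages)
  a <- mean(vals) - b * mean(ages)
  expect_equal(norm$slope, b, tolerance = 1e-10)
  expect_equal(norm$intercept, a, tolerance = 1e-10)
  # a subject on the fitted line scores 0; one residual SD above scores 1
  expect_equal(w_score(a + b * 70, 70, norm), 0)
  expect_equal(w_score(a + b * 70 + norm$resid_sd, 70, norm), 1)
  # control sample scores have mean 0 and unit SD (up to df scaling)
  w <- w_score(vals, ages, norm)
  expect_equal(mean(w), 0, tolerance = 1e-10)
  expect_equal(sd(w) * sqrt(16 / 15), 1, tolerance = 1e-10)
  expect_error(fit_control_norm(c(1, 2, 3), c(70, 70, 70)),
               class = "alphamark_norm")
})

test_that("group summary mirrors hand-computed demographics", {
  rec <- tibble::tibble(
    group = factor(c("low", "low", "high"), levels = c("low", "middle", "high")),
    alpha3_alpha2 = c(0.9, 0.94, 1.3),
    age = c(70, 74, 66), sex = c("F", "M", "F")
  )
  out <- group_summary(rec)
  lowr <- out[out$group == "low" & out$variable == "alpha3_alpha2", ]
  expect_equal(lowr$mean, 0.92)
  expect_equal(lowr$sd, sd(c(0.9, 0.94)))
  expect_equal(c(lowr$min, lowr$max), c(0.9, 0.94))
  highr <- out[out$group == "high" & out$variable == "age", ]
  expect_equal(highr$sd, 0)
  expect_true(highr$sd_degenerate)
  expect_error(group_summary(rec[0, ]), class = "alphamark_summary")
})
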