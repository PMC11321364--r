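test_that("AC/DC and ratio of ratios follow their defining arithmetic", {
  expect_equal(ac_dc(0.5, 0.75), 0.5)
  expect_equal(ac_dc(0.3, 0.3), 0)
  expect_error(ac_dc(0, 0.5), "positive")
  expect_equal(ratio_of_ratios(0.2, 0.2), 1)
  expect_equal(ratio_of_ratios(0.4398, 0.2748), 1.6005, tolerance = 1e-4)
  expect_equal(ratio_of_ratios(0.0586, 0.2585), 0.2267, tolerance = 1e-4)
  expect_error(ratio_of_ratios(0.1, 0), "nonzero")
})

test_that("acdc_table pivots a transmittance grid and flags inverted pulses", {
  tbl <- tidyr::expand_grid(skin = "light", sao2 = c(70, 75),
                            wavelength = c(660, 940),
                            phase = c("systole", "diastole"))
  tbl$transmittance <- c(0.5, 0.75, 0.4, 0.5,   # sao2 70: Is < Id
                         0.6, 0.5, 0.4, 0.5)    # sao2 75: 660 inverted
  out <- acdc_table(tbl)
  expect_equal(nrow(out), 2)
  expect_equal(out$acdc_660[out$sao2 == 70], 0.5)
  expect_equal(out$R[out$sao2 == 70], 0.5 / 0.25)
  expect_true(out$flagged[out$sao2 == 75])
  expect_false(out$flagged[out$sao2 == 70])
  expect_error(acdc_table(tbl[tbl$wavelength == 660, ]), "incomplete")
})

test_that("noiseless linear data is recovered to machine precision", {
  R <- seq(0.2, 1.6, length.out = 7)
  pts <- tibble::tibble(R = R, sao2 = 109 - 25.95 * R)
  cv <- fit_calibration(pts, label = "synthetic")
  expect_equal(cv$intercept, 109, tolerance = 1e-10)
  expect_equal(cv$slope, -25.95, tolerance = 1e-10)
  expect_equal(glance(cv)$r.squared, 1, tolerance = 1e-10)
  expect_error(fit_calibration(tibble::tibble(R = rep(1, 3), sao2 = 1:3)),
               "degenerate")
})

test_that("fits on the tabulated AC/DC data recover the published coefficients", {
  t2 <- load_fixture("table2_acdc")
  wide <- tidyr::pivot_wider(t2, names_from = "wavelength",
                             values_from = "acdc", names_prefix = "w")
  printed <- list(light = c(109.0, -25.95), moderate = c(109.2, -32.69),
                  dark = c(110.6, -50.31))
  for (s in names(printed)) {
    d <- wide[wide$skin == s, ]
    R <- d$w660 / d$w940
    cv <- fit_calibration(tibble::tibble(R = R, sao2 = d$sao2))
    # cross-check lm against the closed-form OLS oracle
    oracle <- ols_oracle(R, d$sao2)
    expect_equal(cv$intercept, oracle[["intercept"]], tolerance = 1e-10)
    expect_equal(cv$slope, oracle[["slope"]], tolerance = 1e-10)
    expect_equal(round(cv$intercept, 1), printed[[s]][1])
    expect_lt(abs(cv$slope - printed[[s]][2]) / abs(printed[[s]][2]), 0.03)
  }
})

test_that("tidy and glance expose coefficients and diagnostics", {
  pts <- tibble::tibble(R = seq(0.3, 1.5, length.out = 7))
  pts$sao2 <- 109 - 25.95 * pts$R + c(0.1, -0.1, 0, 0.05, -0.05, 0, 0)
  cv <- fit_calibration(pts, label = "light")
  td <- tidy(cv)
  expect_equal(td$term, c("(Intercept)", "R"))
  expect_true(all(td$std.error > 0))
  gl <- glance(cv)
  expect_equal(gl$label, "light")
  expect_equal(gl$n_points, 7L)
  expect_gt(gl$r.squared, 0.99)
})

test_that("the commercial relation and curve inversion are mutually consistent", {
  expect_equal(commercial_spo2(0), 110)
  expect_equal(commercial_spo2(4.4), 0)
  expect_equal(pulseoxmc:::round_half_up(commercial_spo2(0.8863), 1), 87.8)
  expect_error(commercial_spo2(-0.1), "nonnegative")
  expect_equal(invert_calibration(light_curve(), 86), 23 / 25.95,
               tolerance = 1e-12)
  expect_equal(invert_calibration(dark_curve(), 100), 10.6 / 50.31,
               tolerance = 1e-12)
  expect_equal(invert_calibration(light_curve(), 109), 0)
  # round trip through the commercial curve is the identity
  for (s in seq(70, 100, by = 5)) {
    expect_equal(commercial_spo2(invert_calibration(commercial_curve(), s)),
                 s, tolerance = 1e-12)
  }
  expect_error(invert_calibration(calibration_curve(109, 0), 90), "slope")
})

test_that("the bias report reproduces the printed light-skin table", {
  rep <- bias_report(light_curve(), 86:92)
  expect_equal(rep$spo2_rounded, c(87.8, 88.8, 89.8, 90.7, 91.7, 92.7, 93.6))
  expect_equal(rep$bias_rounded, c(1.8, 1.8, 1.8, 1.7, 1.7, 1.7, 1.6))
  expect_equal(mean_bias(rep, rounded = TRUE), 1.7)
  expect_equal(mean_bias(rep), mean(rep$bias))
})

test_that("a curve identical to the commercial relation has zero bias", {
  rep <- bias_report(commercial_curve(), 86:92)
  expect_equal(rep$bias, rep(0, 7))
  expect_error(bias_report(light_curve(), numeric()), "empty")
  expect_error(bias_report(light_curve(), 60:65), "70")
})

test_that("cohort bias ratios divide darker by lighter mean bias", {
  expect_equal(cohort_bias_ratio(0.5, 3.3), 6.6)
  r <- bias_report(light_curve(), 86:92)
  expect_equal(cohort_bias_ratio(r, r), 1)
  expect_error(cohort_bias_ratio(0, 3), "zero")
})

test_that("reference multipliers at full saturation match the published factors", {
  expect_equal(round(reference_multiplier(light_curve(), moderate_curve())$factor,
                     2), 1.23)
  expect_equal(round(reference_multiplier(light_curve(), dark_curve())$factor,
                     2), 1.65)
  expect_equal(reference_multiplier(light_curve(), light_curve())$factor, 1)
})

test_that("the light/dark multiplier profile matches its closed-form values", {
  cf <- multiplier_profile(light_curve(), dark_curve())
  # oracle: ((109 - s)/25.95) / ((110.6 - s)/50.31) on the grid
  s <- seq(70, 100, by = 5)
  oracle <- ((109 - s) / 25.95) / ((110.6 - s) / 50.31)
  expect_equal(cf$profile$factor, oracle, tolerance = 1e-12)
  expect_equal(round(cf$profile$factor, 3),
               c(1.862, 1.852, 1.837, 1.818, 1.788, 1.740, 1.646))
  expect_equal(cf$factor, mean(oracle))
  expect_lt(abs(cf$factor - 1.8), 0.05)
  # the profile grows towards high saturation (the exponential trend)
  expect_true(all(diff(cf$profile$factor) < 0))  # listed from 70% upwards
})

test_that("one-point profiles collapse to the reference multiplier", {
  one <- multiplier_profile(light_curve(), dark_curve(), 100)
  expect_equal(one$factor,
               reference_multiplier(light_curve(), dark_curve())$factor)
})

test_that("curves with proportional slopes have a constant profile", {
  a <- calibration_curve(108, -30)
  b <- calibration_curve(108, -30 / 1.5)   # R_b = 1.5 R_a ... ratio 1/1.5
  cf <- multiplier_profile(a, b, seq(70, 100, by = 5))
  expect_equal(cf$profile$factor, rep(1 / 1.5, 7), tolerance = 1e-12)
  expect_equal(cf$factor, 1 / 1.5, tolerance = 1e-12)
})

test_that("applying a multiplier rescales the slope exactly", {
  adj <- apply_multiplier(dark_curve(), 1.7919)
  expect_equal(adj$intercept, 110.6)
  expect_equal(adj$slope, -50.31 / 1.7919, tolerance = 1e-12)
  expect_equal(apply_multiplier(dark_curve(), 1)$slope, dark_curve()$slope)
  expect_error(apply_multiplier(dark_curve(), -1), "positive")
  # on raw points: scaling R by f then refitting gives (a, b / f)
  R <- seq(0.2, 0.8, length.out = 7)
  pts <- tibble::tibble(R = R, sao2 = 110.6 - 50.31 * R)
  refit <- apply_multiplier(pts, 2)
  expect_equal(refit$intercept, 110.6, tolerance = 1e-9)
  expect_equal(refit$slope, -50.31 / 2, tolerance = 1e-9)
})

test_that("multiplier-adjusted curves align with the light-skin relation", {
  # moderate with its linear factor: saturation read at equal R agrees with
  # the light curve to better than one percentage point over 90-100%
  f_mod <- reference_multiplier(light_curve(), moderate_curve())
  adj_mod <- apply_multiplier(moderate_curve(), f_mod)
  R90 <- invert_calibration(light_curve(), seq(90, 100, by = 1))
  gap_mod <- predict(adj_mod, R90) - predict(light_curve(), R90)
  expect_lt(max(abs(gap_mod)), 1)
  # dark needs the mean of the full profile; the same alignment criterion
  f_dark <- multiplier_profile(light_curve(), dark_curve())
  adj_dark <- apply_multiplier(dark_curve(), f_dark)
  gap_dark <- predict(adj_dark, R90) - predict(light_curve(), R90)
  expect_lt(max(abs(gap_dark)), 1)
})
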