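test_that("specular reflectance matches the normal-incidence Fresnel formula", {
  expect_equal(specular_reflectance(1.0, 1.4), (0.4 / 2.4)^2,
               tolerance = 1e-12)
  expect_equal(specular_reflectance(1.0, 1.0), 0)
  expect_equal(specular_reflectance(1.4, 1.0), specular_reflectance(1.0, 1.4))
})

test_that("Fresnel reflectance handles normal incidence, TIR and matched media", {
  expect_equal(fresnel_reflectance(1.4, 1.0, 1.0), ((1.4 - 1) / (1.4 + 1))^2,
               tolerance = 1e-12)
  # beyond the critical angle asin(1/1.4): total internal reflection
  cos_crit <- cos(asin(1 / 1.4))
  expect_equal(fresnel_reflectance(1.4, 1.0, cos_crit * 0.99), 1.0)
  expect_equal(fresnel_reflectance(1.4, 1.4, 0.3), 0)
  # grazing exit approaches full reflection
  expect_gt(fresnel_reflectance(1.0, 1.4, 0.01), 0.9)
})

test_that("free paths are exponential with the right mean", {
  for (mu_t in c(0.5, 10)) {
    s <- sample_free_path(mu_t, n = 1e6, seed = 11)
    expect_lt(abs(mean(s) - 1 / mu_t), 3 * se_mean(s))
  }
})

test_that("Henyey-Greenstein sampling has first moment g", {
  for (g in c(0, 0.5, 0.91, 0.94)) {
    ct <- sample_hg_deflection(g, n = 1e6, seed = 5)
    expect_true(all(abs(ct) <= 1))
    expect_lt(abs(mean(ct) - g), 3 * se_mean(ct))
  }
})

test_that("direction updates preserve unit norm and limiting cases", {
  expect_equal(update_direction(c(0, 0, 1), 1, 0.3), c(0, 0, 1),
               tolerance = 1e-12)
  expect_equal(update_direction(c(0, 0, 1), -1, 1.2), c(0, 0, -1),
               tolerance = 1e-9)
  d <- c(0.3, -0.5, sqrt(1 - 0.09 - 0.25))
  set.seed(42)
  for (i in 1:200) {
    d <- update_direction(d, runif(1, -1, 1), runif(1, 0, 2 * pi))
    expect_lt(abs(sqrt(sum(d^2)) - 1), 1e-9)
  }
})

test_that("the Gaussian source has position SD of half the beam radius", {
  xy <- sample_source_positions(source_spec(radius = 1), n = 1e5, seed = 3)
  sd_se <- 0.5 / sqrt(2 * (1e5 - 1))  # SE of a normal SD estimate
  expect_lt(abs(sd(xy[, 1]) - 0.5), 3 * sd_se)
  expect_lt(abs(sd(xy[, 2]) - 0.5), 3 * sd_se)
})

test_that("roulette preserves expected weight and spares heavy packets", {
  w <- pulseoxmc:::cpp_roulette(1e-5, 1e-4, 0.1, 1e6, 7)
  expect_setequal(unique(w), c(0, 1e-4))
  expect_lt(abs(mean(w) - 1e-5), 3 * se_mean(w))
  expect_equal(unique(pulseoxmc:::cpp_roulette(0.5, 1e-4, 0.1, 100, 7)), 0.5)
  # survival 1 never terminates and never inflates
  expect_equal(unique(pulseoxmc:::cpp_roulette(1e-6, 1e-4, 1, 100, 7)), 1e-6)
})

test_that("ray-cylinder intersections match the closed-form quadratic", {
  z0 <- 6.5; r <- 2
  set.seed(99)
  for (i in 1:100) {
    p <- c(runif(1, -6, 6), runif(1, 0, 13))
    ang <- runif(1, 0, 2 * pi)
    u <- c(cos(ang), sin(ang))
    inside <- (p[1]^2 + (p[2] - z0)^2) < r^2
    got <- pulseoxmc:::cpp_cylinder_distance(p[1], p[2], u[1], u[2],
                                             z0, r, inside)
    # oracle: roots of |p + t u - c|^2 = r^2
    b <- 2 * (p[1] * u[1] + (p[2] - z0) * u[2])
    cc <- p[1]^2 + (p[2] - z0)^2 - r^2
    disc <- b^2 - 4 * cc
    if (disc <= 0) {
      expect_equal(got, Inf)
    } else {
      roots <- sort(c((-b - sqrt(disc)) / 2, (-b + sqrt(disc)) / 2))
      pos <- roots[roots > 1e-12]
      if (inside) {
        expect_equal(got, max(roots), tolerance = 1e-9)
      } else if (length(pos) == 2) {
        expect_equal(got, pos[1], tolerance = 1e-9)
      } else {
        expect_equal(got, Inf)
      }
    }
  }
})

test_that("an absorbing slab reproduces Beer-Lambert transmittance", {
  cases <- list(c(mu_a = 1, L = 1), c(mu_a = 0.5, L = 2), c(mu_a = 2, L = 0.5))
  n <- 1e5
  for (cs in cases) {
    ph <- make_homogeneous_phantom(cs[["mu_a"]], 0, 0, cs[["L"]])
    tl <- run_simulation(ph, detector = detector_spec(radius = Inf),
                         config = run_config(target_detected = 1,
                                             max_launched = n,
                                             batch_size = n, seed = 17))
    p <- exp(-cs[["mu_a"]] * cs[["L"]])
    se <- sqrt(p * (1 - p) / n)
    expect_equal(tl$launched, n)
    expect_lt(abs(transmittance(tl) - p), 3 * se)
    expect_lt(abs(conservation_error(tl)), 1e-9)
  }
})

test_that("a ballistic run detects exactly the packets launched inside the aperture", {
  # no interaction, matched index: straight rays; detection probability is
  # the Gaussian mass within the detector radius, 1 - exp(-r^2 / (2 sigma^2))
  ph <- make_homogeneous_phantom(0, 0, 0, 5)
  n <- 1e5
  tl <- run_simulation(ph, source_spec(radius = 1),
                       detector_spec(radius = 1),
                       run_config(target_detected = 1, max_launched = n,
                                  batch_size = n, seed = 23))
  p <- 1 - exp(-1 / (2 * 0.25))
  expect_lt(abs(transmittance(tl) - p), 3 * sqrt(p * (1 - p) / n))
  # everything not detected escaped; nothing absorbed
  expect_equal(tl$absorbed_weight, 0)
  expect_equal(tl$detected_weight + tl$escaped_weight, tl$launched)
})

test_that("weight is conserved in a scattering slab with mismatched index", {
  ph <- make_homogeneous_phantom(0, 10, 0.9, 5, refractive_index = 1.4)
  tl <- run_simulation(ph, detector = detector_spec(radius = Inf),
                       config = run_config(target_detected = 1,
                                           max_launched = 2e4,
                                           batch_size = 2e4, seed = 31))
  expect_equal(tl$absorbed_weight, 0)
  expect_lt(abs(conservation_error(tl)), 1e-9)
  expect_gt(tl$specular_weight, 0)
})

test_that("a fixed seed reproduces the tally bit for bit", {
  st <- build_finger_model("moderate", hemodynamic_state(0.85, "systole"))
  cfg <- run_config(target_detected = 200, batch_size = 2000, seed = 101,
                    importance_spacing = 1.3)
  a <- run_simulation(st, config = cfg, wavelength = 940)
  b <- run_simulation(st, config = cfg, wavelength = 940)
  for (f in c("launched", "specular_weight", "absorbed_weight",
              "detected_weight", "detected_count", "escaped_weight",
              "residual_weight", "batches")) {
    expect_identical(a[[f]], b[[f]])
  }
  # a different seed gives a different transport history
  c2 <- run_config(target_detected = 200, batch_size = 2000, seed = 102,
                   importance_spacing = 1.3)
  d <- run_simulation(st, config = c2, wavelength = 940)
  expect_false(identical(a$detected_weight, d$detected_weight))
})

test_that("per-batch substreams make merged batches equal the single run", {
  st <- build_finger_model("light", hemodynamic_state(0.9, "diastole"))
  bs <- 2000
  whole <- tryCatch(
    run_simulation(st, config = run_config(target_detected = 1e9,
                                           max_launched = 3 * bs,
                                           batch_size = bs, seed = 7),
                   wavelength = 940, stream_base = 50),
    pulseoxmc_budget_exhausted = function(e) e$tally)
  expect_equal(whole$launched, 3 * bs)
  parts <- lapply(0:2, function(k) {
    tryCatch(
      run_simulation(st, config = run_config(target_detected = 1e9,
                                             max_launched = bs,
                                             batch_size = bs, seed = 7),
                     wavelength = 940, stream_base = 50 + k),
      pulseoxmc_budget_exhausted = function(e) e$tally)
  })
  for (f in c("specular_weight", "absorbed_weight", "detected_weight",
              "escaped_weight", "residual_weight")) {
    expect_equal(sum(vapply(parts, `[[`, numeric(1), f)), whole[[f]],
                 tolerance = 1e-12)
  }
  expect_equal(sum(vapply(parts, `[[`, numeric(1), "detected_count")),
               whole$detected_count)
})

test_that("budget exhaustion raises a typed error carrying the partial tally", {
  ph <- make_homogeneous_phantom(20, 0, 0, 5)  # opaque: nothing gets through
  err <- tryCatch(
    run_simulation(ph, detector = detector_spec(radius = Inf),
                   config = run_config(target_detected = 10,
                                       max_launched = 1000,
                                       batch_size = 1000, seed = 1)),
    pulseoxmc_budget_exhausted = function(e) e)
  expect_s3_class(err, "pulseoxmc_budget_exhausted")
  expect_equal(err$tally$launched, 1000)
  expect_equal(err$tally$detected_count, 0)
})

test_that("importance splitting leaves the transmittance estimate unbiased", {
  # same slab with and without importance planes; estimates must agree
  # within combined Monte Carlo uncertainty
  ph <- make_homogeneous_phantom(0.1, 5, 0.9, 5)
  plain <- run_simulation(ph, detector = detector_spec(radius = Inf),
                          config = run_config(target_detected = 1,
                                              max_launched = 4e4,
                                              batch_size = 4e4, seed = 13))
  split <- run_simulation(ph, detector = detector_spec(radius = Inf),
                          config = run_config(target_detected = 1,
                                              max_launched = 4e4,
                                              batch_size = 4e4, seed = 14,
                                              importance_spacing = 1))
  expect_lt(abs(conservation_error(split)), 1e-9)
  expect_lt(abs(transmittance(plain) - transmittance(split)),
            0.05 * transmittance(plain))
  # splitting multiplies the number of detection events
  expect_gt(split$detected_count, plain$detected_count)
})

test_that("transmittance guards its domain", {
  st <- build_finger_model("light", hemodynamic_state(0.9, "diastole"))
  tl <- run_simulation(st, config = run_config(target_detected = 50,
                                               batch_size = 1000, seed = 2,
                                               importance_spacing = 1.3),
                       wavelength = 660)
  expect_gt(transmittance(tl), 0)
  expect_lt(transmittance(tl), 1)
  expect_error(transmittance(structure(list(launched = 0),
                                       class = "mc_tally")), "launched")
})
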