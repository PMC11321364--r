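#' Experiment configuration for the simulation grid
#'
#' Describes the full factorial grid (phototypes x SaO2 x cardiac phase x
#' wavelength) and the photon budget. Two presets are provided: `"paper"`
#' (10^6 detected packets per condition, the full-study budget) and `"ci"`
#' (10^4, a reduced budget for fast runs whose ordering/sign conclusions
#' remain stable).
#'
#' @param phenotypes Tibble from [skin_phenotypes()] (or labels).
#' @param sao2_grid Arterial saturations in percent, within `[70, 100]`.
#' @param wavelengths Wavelengths in nm.
#' @param preset `"paper"` or `"ci"`; sets `photons` unless given.
#' @param photons Target detected packets per condition (overrides preset).
#' @param seed Base RNG seed; every condition derives a disjoint substream.
#' @param max_launched Per-condition launch cap.
#' @param batch_size Packets per RNG substream.
#' @param total_thickness Finger thickness (mm).
#' @param layer_overrides Optional layer-geometry override tibble, see
#'   [build_finger_model()].
#' @param bone_radius Bone cylinder radius (mm).
#' @param source_radius,detector_radius Beam and detector radii (mm).
#' @param roulette_threshold,roulette_survival Roulette parameters.
#' @param importance_spacing Importance-plane spacing (mm) for the
#'   weight-window variance reduction; see [run_config()].
#' @param out_dir Output directory for [write_tables()].
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(phenotypes = skin_phenotypes(),
                              sao2_grid = seq(70, 100, by = 5),
                              wavelengths = c(660, 940),
                              preset = c("ci", "paper"),
                              photons = NULL,
                              seed = 1,
                              max_launched = 1e9,
                              batch_size = 1e4,
                              total_thickness = 13,
                              layer_overrides = NULL,
                              bone_radius = 2,
                              source_radius = 1.0,
                              detector_radius = 1.0,
                              roulette_threshold = 1e-4,
                              roulette_survival = 0.1,
                              importance_spacing = 1.3,
                              out_dir = ".") {
  preset <- match.arg(preset)
  if (is.character(phenotypes)) phenotypes <- skin_phenotypes(phenotypes)
  stopifnot(all(c("skin", "vmel") %in% names(phenotypes)),
            all(phenotypes$vmel >= 0), all(phenotypes$vmel <= 1))
  if (length(sao2_grid) == 0 || any(sao2_grid < 70 | sao2_grid > 100)) {
    stop("sao2_grid must be nonempty and lie within [70, 100]",
         call. = FALSE)
  }
  if (length(wavelengths) == 0) stop("wavelengths must be nonempty",
                                     call. = FALSE)
  if (is.null(photons)) {
    photons <- switch(preset, paper = 1e6, ci = 1e4)
  }
  structure(list(
    phenotypes = phenotypes, sao2_grid = sao2_grid,
    wavelengths = wavelengths, preset = preset, photons = photons,
    seed = seed, max_launched = max_launched, batch_size = batch_size,
    total_thickness = total_thickness, layer_overrides = layer_overrides,
    bone_radius = bone_radius, source_radius = source_radius,
    detector_radius = detector_radius,
    roulette_threshold = roulette_threshold,
    roulette_survival = roulette_survival,
    importance_spacing = importance_spacing, out_dir = out_dir
  ), class = "experiment_config")
}

# disjoint RNG substream block per condition: up to 2^20 batches each
condition_stream_base <- function(condition_index) {
  (condition_index - 1) * 2^20
}

#' Run the full simulation grid
#'
#' Simulates transmittance for every (phototype, SaO2, phase, wavelength)
#' condition. Each condition owns an independent RNG substream derived from
#' the base seed and the condition index, so the table is deterministic for
#' a fixed seed and independent of evaluation order.
#'
#' @param config An [experiment_config()].
#' @param progress Print one line per condition.
#' @return A tibble with one row per condition: `skin`, `vmel`, `sao2`,
#'   `phase`, `wavelength`, `launched`, `detected_count`, `detected_weight`,
#'   `transmittance`, `batches`, `conservation_error`.
#' @export
run_grid <- function(config = experiment_config(), progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  grid <- tidyr::expand_grid(
    skin = as.character(config$phenotypes$skin),
    sao2 = config$sao2_grid,
    phase = c("diastole", "systole"),
    wavelength = config$wavelengths
  )
  grid$vmel <- config$phenotypes$vmel[match(grid$skin,
                                            config$phenotypes$skin)]
  src <- source_spec(config$source_radius)
  det <- detector_spec(config$detector_radius)
  rc <- run_config(target_detected = config$photons,
                   max_launched = config$max_launched,
                   roulette_threshold = config$roulette_threshold,
                   roulette_survival = config$roulette_survival,
                   seed = config$seed, batch_size = config$batch_size,
                   importance_spacing = config$importance_spacing)

  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    state <- hemodynamic_state(row$sao2 / 100, row$phase)
    stack <- build_finger_model(
      config$phenotypes[config$phenotypes$skin == row$skin, ],
      state,
      wavelengths = row$wavelength,
      total_thickness = config$total_thickness,
      layer_overrides = config$layer_overrides,
      bone_radius = config$bone_radius)
    tl <- tryCatch(
      run_simulation(stack, src, det, rc, wavelength = row$wavelength,
                     stream_base = condition_stream_base(i)),
      pulseoxmc_budget_exhausted = function(e) {
        stop("condition ", row$skin, "/", row$sao2, "%/", row$phase, "/",
             row$wavelength, " nm: ", conditionMessage(e), call. = FALSE)
      })
    if (progress) {
      message(sprintf("%-8s SaO2=%3d%% %-8s %d nm: T=%.3e (%d launched)",
                      row$skin, row$sao2, row$phase, row$wavelength,
                      transmittance(tl), tl$launched))
    }
    dplyr::bind_cols(row, tibble::tibble(
      launched = tl$launched,
      detected_count = tl$detected_count,
      detected_weight = tl$detected_weight,
      transmittance = transmittance(tl),
      batches = tl$batches,
      conservation_error = conservation_error(tl)
    ))
  })
  res
}

#' Assemble calibration analytics from a transmittance grid
#'
#' Turns the raw per-condition transmittance table into the full analysis:
#' AC/DC table and ratio of ratios per skin x SaO2, least-squares
#' calibration curve per phototype, bias reports over SaO2 86-92% against
#' the commercial relation, the dark/light mean-bias ratio, and the
#' skin-tone correction multipliers (linear at SaO2 = 100 and the
#' mean-of-profile factor over the full grid).
#'
#' @param raw Tibble from [run_grid()] (columns `skin`, `sao2`, `phase`,
#'   `wavelength`, `transmittance`).
#' @param bias_range True-SaO2 range for the bias table.
#' @param metadata Optional list stored in the result (seed, config hash).
#' @return An `experiment_result` list: `raw`, `acdc`, `curves`,
#'   `curve_summary`, `bias`, `bias_ratio`, `multipliers`,
#'   `adjusted_curves`, `metadata`.
#' @export
assemble_tables <- function(raw, bias_range = 86:92, metadata = list()) {
  skins <- unique(as.character(raw$skin))
  sao2s <- unique(raw$sao2)
  expected <- tidyr::expand_grid(skin = skins, sao2 = sao2s,
                                 phase = c("diastole", "systole"),
                                 wavelength = unique(raw$wavelength))
  got <- dplyr::count(raw, .data$skin, .data$sao2, .data$phase,
                      .data$wavelength)
  gaps <- dplyr::anti_join(
    expected, got[got$n == 1, c("skin", "sao2", "phase", "wavelength")],
    by = c("skin", "sao2", "phase", "wavelength"))
  if (nrow(gaps) > 0 || any(got$n != 1)) {
    stop("incomplete or duplicated grid; missing/duplicated conditions: ",
         paste(utils::head(paste(gaps$skin, gaps$sao2, gaps$phase,
                                 gaps$wavelength, sep = "/"), 10),
               collapse = ", "), call. = FALSE)
  }

  acdc <- acdc_table(raw)
  skins <- intersect(c("light", "moderate", "dark"), skins)
  curves <- purrr::map(
    stats::setNames(skins, skins),
    function(s) fit_calibration(acdc[acdc$skin == s, c("R", "sao2")],
                                label = s))
  curve_summary <- purrr::map_dfr(curves, glance)

  bias <- purrr::map(curves, bias_report, sao2_range = bias_range)
  bias_ratio <- if (all(c("light", "dark") %in% skins)) {
    cohort_bias_ratio(bias$light, bias$dark)
  } else NA_real_

  multipliers <- NULL
  adjusted <- NULL
  if (all(c("light", "dark") %in% skins)) {
    multipliers <- list(
      profile_dark = multiplier_profile(curves$light, curves$dark,
                                        sort(sao2s)))
    if ("moderate" %in% skins) {
      multipliers$moderate <- reference_multiplier(curves$light,
                                                   curves$moderate)
    }
    multipliers$dark <- reference_multiplier(curves$light, curves$dark)
    adjusted <- list(
      dark = apply_multiplier(curves$dark, multipliers$profile_dark))
    if ("moderate" %in% skins) {
      adjusted$moderate <- apply_multiplier(curves$moderate,
                                            multipliers$moderate)
    }
  }

  structure(list(raw = raw, acdc = acdc, curves = curves,
                 curve_summary = curve_summary, bias = bias,
                 bias_ratio = bias_ratio, multipliers = multipliers,
                 adjusted_curves = adjusted, metadata = metadata),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  if (!is.null(x$curve_summary)) {
    cat("calibration curves:\n")
    print(x$curve_summary)
  }
  if (!is.null(x$bias_ratio) && !is.na(x$bias_ratio)) {
    cat(sprintf("dark/light mean-bias ratio: %.3g\n", x$bias_ratio))
  }
  invisible(x)
}

#' Deterministic analytics from the packaged fixtures
#'
#' Runs the entire calibration/bias/correction analysis with zero Monte
#' Carlo, from the packaged tables: the simulated-study AC/DC table, the
#' published calibration-equation coefficients, and the clinical cohort
#' table. Useful as a closed-form cross-check of the analytics and as the
#' deterministic half of the pipeline.
#'
#' @param bias_range True-SaO2 range for the bias table (default 86-92%).
#' @return An `experiment_result`-like list with elements `acdc`,
#'   `fitted_curves` (least squares on fixture-derived R), `printed_curves`
#'   (published coefficients), `bias` (light and dark, from the printed
#'   curves, against the commercial relation), `bias_ratio`, `clinical`
#'   (cohort table with printed and recomputed mean biases and their
#'   ratios), `multipliers`, and `adjusted_curves`.
#' @export
#' @examples
#' res <- analytics_from_fixtures()
#' mean_bias(res$bias$light, rounded = TRUE)  # 1.7
analytics_from_fixtures <- function(bias_range = 86:92) {
  t2 <- load_fixture("table2_acdc")
  acdc <- t2 |>
    tidyr::pivot_wider(names_from = "wavelength", values_from = "acdc",
                       names_prefix = "acdc_") |>
    dplyr::mutate(R = ratio_of_ratios(.data$acdc_660, .data$acdc_940))

  skins <- c("light", "moderate", "dark")
  fitted <- purrr::map(
    stats::setNames(skins, skins),
    function(s) fit_calibration(acdc[acdc$skin == s, c("R", "sao2")],
                                label = s))

  cf <- load_fixture("calibration_coefficients")
  printed <- purrr::map(
    stats::setNames(cf$curve, cf$curve),
    function(cv) {
      row <- cf[cf$curve == cv, ]
      calibration_curve(row$intercept, row$slope, label = cv)
    })

  bias <- list(
    light = bias_report(printed$light, bias_range),
    dark = bias_report(printed$dark, bias_range))
  bias_ratio <- cohort_bias_ratio(bias$light, bias$dark)

  t3 <- load_fixture("table3_cohort")
  t3s <- load_fixture("table3_summary")
  printed_means <- stats::setNames(t3s$mean_bias_printed, t3s$cohort)
  recomputed <- tapply(t3$bias_mean, t3$cohort, mean)
  clinical <- list(
    table = t3,
    mean_bias_printed = printed_means,
    mean_bias_recomputed = recomputed,
    ratio_printed = unname(printed_means[["black"]] /
                             printed_means[["white"]]),
    ratio_recomputed = unname(recomputed[["black"]] / recomputed[["white"]]))

  multipliers <- list(
    moderate = reference_multiplier(printed$light, printed$moderate),
    dark = reference_multiplier(printed$light, printed$dark),
    profile_dark = multiplier_profile(printed$light, printed$dark))
  adjusted <- list(
    moderate = apply_multiplier(printed$moderate, multipliers$moderate),
    dark = apply_multiplier(printed$dark, multipliers$profile_dark))

  structure(list(acdc = acdc, fitted_curves = fitted,
                 printed_curves = printed, bias = bias,
                 bias_ratio = bias_ratio, clinical = clinical,
                 multipliers = multipliers, adjusted_curves = adjusted,
                 metadata = list(source = "packaged fixtures")),
            class = "experiment_result")
}
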