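#' Pulsatile AC/DC perfusion index
#'
#' `(Id - Is) / Is` from diastolic and systolic transmitted intensities.
#' Physically `Is <= Id` (systolic blood absorbs more); records violating
#' this are computed anyway and flagged by [acdc_table()], not dropped.
#'
#' @param i_systolic,i_diastolic Systolic and diastolic intensities
#'   (vectorised).
#' @return The AC/DC ratio.
#' @export
#' @examples
#' ac_dc(0.5, 0.75)  # 0.5
ac_dc <- function(i_systolic, i_diastolic) {
  if (any(i_systolic <= 0)) stop("systolic intensity must be positive",
                                 call. = FALSE)
  (i_diastolic - i_systolic) / i_systolic
}

#' Ratio of ratios
#'
#' `R = (AC/DC at 660 nm) / (AC/DC at 940 nm)`, the quantity pulse oximeters
#' calibrate against arterial saturation.
#'
#' @param acdc_660,acdc_940 AC/DC values at the red and infrared
#'   wavelengths.
#' @return R (vectorised).
#' @export
ratio_of_ratios <- function(acdc_660, acdc_940) {
  if (any(acdc_940 == 0)) stop("infrared AC/DC must be nonzero",
                               call. = FALSE)
  acdc_660 / acdc_940
}

#' AC/DC and ratio-of-ratios table from a transmittance grid
#'
#' Pivots a long per-condition transmittance table (one row per skin x SaO2
#' x phase x wavelength) into one row per skin x SaO2 with `acdc_660`,
#' `acdc_940`, and `R`. Rows where systolic transmittance exceeds diastolic
#' at either wavelength are kept and marked in `flagged`.
#'
#' @param transmittance_tbl Tibble with columns `skin`, `sao2`,
#'   `wavelength`, `phase`, `transmittance`.
#' @return A tibble with columns `skin`, `sao2`, `acdc_660`, `acdc_940`,
#'   `R`, `flagged`.
#' @export
acdc_table <- function(transmittance_tbl) {
  needed <- c("skin", "sao2", "wavelength", "phase", "transmittance")
  stopifnot(all(needed %in% names(transmittance_tbl)))
  wide <- transmittance_tbl |>
    dplyr::select(dplyr::all_of(needed)) |>
    tidyr::pivot_wider(names_from = c("wavelength", "phase"),
                       values_from = "transmittance")
  req <- c("660_systole", "660_diastole", "940_systole", "940_diastole")
  missing <- setdiff(req, names(wide))
  if (length(missing)) {
    stop("transmittance grid is incomplete; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  wide |>
    dplyr::mutate(
      acdc_660 = ac_dc(.data[["660_systole"]], .data[["660_diastole"]]),
      acdc_940 = ac_dc(.data[["940_systole"]], .data[["940_diastole"]]),
      R = ratio_of_ratios(.data$acdc_660, .data$acdc_940),
      flagged = .data$acdc_660 < 0 | .data$acdc_940 < 0
    ) |>
    dplyr::select(dplyr::all_of(c("skin", "sao2", "acdc_660", "acdc_940",
                                  "R", "flagged")))
}

#' Construct a linear calibration curve
#'
#' The linear relation `SaO2 = a + b R` (saturation in percent).
#'
#' @param intercept Intercept `a` in percent.
#' @param slope Slope `b` in percent per unit R.
#' @param label Optional curve label (e.g. a skin phototype).
#' @param fit Optional `lm` object the coefficients came from.
#' @param n_points Number of points behind the fit.
#' @return A `calibration_curve` object.
#' @export
calibration_curve <- function(intercept, slope, label = NA_character_,
                              fit = NULL, n_points = NA_integer_) {
  structure(list(intercept = intercept, slope = slope, label = label,
                 fit = fit, n_points = n_points),
            class = "calibration_curve")
}

#' The commercial pulse-oximeter relation
#'
#' `SpO2 = 110 - 25 R`, the widely used commercial calibration all skin
#' types are compared against.
#'
#' @return A `calibration_curve` with intercept 110 and slope -25.
#' @export
commercial_curve <- function() {
  calibration_curve(110, -25, label = "commercial")
}

#' Fit a calibration curve by least squares
#'
#' Ordinary least squares of SaO2 (%) on the ratio of ratios R, the
#' line-of-best-fit route to a per-phototype calibration.
#'
#' @param points Tibble (or data frame) with columns `R` and `sao2`.
#' @param label Optional curve label.
#' @return A `calibration_curve` carrying the `lm` fit and diagnostics.
#' @export
#' @examples
#' pts <- tibble::tibble(R = seq(0.2, 1.5, length.out = 7),
#'                       sao2 = 109 - 25.95 * seq(0.2, 1.5, length.out = 7))
#' fit_calibration(pts)
fit_calibration <- function(points, label = NA_character_) {
  stopifnot(all(c("R", "sao2") %in% names(points)), nrow(points) >= 2)
  if (length(unique(points$R)) < 2) {
    stop("degenerate fit: all R values are identical", call. = FALSE)
  }
  fit <- stats::lm(sao2 ~ R, data = points)
  cf <- stats::coef(fit)
  calibration_curve(unname(cf[1]), unname(cf[2]), label = label,
                    fit = fit, n_points = nrow(points))
}

#' @export
print.calibration_curve <- function(x, ...) {
  lbl <- if (is.na(x$label)) "" else paste0(" [", x$label, "]")
  cat(sprintf("<calibration_curve>%s SaO2 = %.4g + (%.4g) R\n",
              lbl, x$intercept, x$slope))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration curve
#'
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @return One row per coefficient (`term`, `estimate`, and, when the curve
#'   was fitted, `std.error`).
#' @export
tidy.calibration_curve <- function(x, ...) {
  out <- tibble::tibble(term = c("(Intercept)", "R"),
                        estimate = c(x$intercept, x$slope))
  if (!is.null(x$fit)) {
    se <- suppressWarnings(summary(x$fit))$coefficients[, "Std. Error"]
    out$std.error <- unname(se)
  }
  out
}

#' One-row summary of a calibration curve
#'
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @return Tibble with `label`, `intercept`, `slope`, `r.squared`, `sigma`,
#'   `n_points`.
#' @export
glance.calibration_curve <- function(x, ...) {
  r2 <- sigma <- NA_real_
  if (!is.null(x$fit)) {
    # summary.lm warns on noiseless synthetic fits; the diagnostics are
    # still well defined
    s <- suppressWarnings(summary(x$fit))
    r2 <- s$r.squared
    sigma <- s$sigma
  }
  tibble::tibble(label = x$label, intercept = x$intercept, slope = x$slope,
                 r.squared = r2, sigma = sigma, n_points = x$n_points)
}

#' Predict saturation from a curve
#'
#' @param object A `calibration_curve`.
#' @param R Ratio-of-ratios values.
#' @param ... Unused.
#' @return Predicted saturation in percent (not clamped).
#' @export
predict.calibration_curve <- function(object, R, ...) {
  object$intercept + object$slope * R
}

#' SpO2 from the commercial relation
#'
#' @param R Ratio of ratios (nonnegative).
#' @return `110 - 25 R`, in percent, not clamped.
#' @export
commercial_spo2 <- function(R) {
  if (any(R < 0)) stop("R must be nonnegative", call. = FALSE)
  110 - 25 * R
}

#' Invert a calibration curve
#'
#' Rearranges `SaO2 = a + b R` to the ratio of ratios a given true
#' saturation corresponds to.
#'
#' @param curve A `calibration_curve`.
#' @param sao2 Saturation in percent (vectorised).
#' @return `R = (sao2 - a) / b`.
#' @export
invert_calibration <- function(curve, sao2) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("curve has zero slope", call. = FALSE)
  (sao2 - curve$intercept) / curve$slope
}

# round half away from zero, the convention of the printed tables
round_half_up <- function(x, digits = 1) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Bias of a phototype curve against a commercial oximeter
#'
#' For each true SaO2, inverts the phototype calibration to its R and maps R
#' through the commercial relation to the SpO2 a commercial device would
#' display; bias is `SpO2 - SaO2`. Rounded (half away from zero, one
#' decimal) columns reproduce the printed-table convention; unrounded values
#' are retained.
#'
#' @param curve A `calibration_curve` for the phototype.
#' @param sao2_range True saturations in percent, within `[70, 100]`.
#' @param commercial The display-device curve; default [commercial_curve()].
#' @return A `bias_report`: a tibble with columns `sao2`, `R`, `spo2`,
#'   `bias`, `spo2_rounded`, `bias_rounded`, and attributes `mean_bias`
#'   (unrounded) and `mean_bias_rounded`.
#' @export
#' @examples
#' light <- calibration_curve(109, -25.95, "light")
#' bias_report(light, 86:92)
bias_report <- function(curve, sao2_range, commercial = commercial_curve()) {
  if (length(sao2_range) == 0) stop("empty saturation range", call. = FALSE)
  if (any(sao2_range < 70 | sao2_range > 100)) {
    stop("sao2_range must lie within [70, 100]", call. = FALSE)
  }
  R <- invert_calibration(curve, sao2_range)
  spo2 <- predict(commercial, R)
  bias <- spo2 - sao2_range
  out <- tibble::tibble(
    sao2 = sao2_range, R = R, spo2 = spo2, bias = bias,
    spo2_rounded = round_half_up(spo2, 1),
    bias_rounded = round_half_up(bias, 1)
  )
  structure(out,
            class = c("bias_report", class(tibble::tibble())),
            label = curve$label,
            mean_bias = mean(bias),
            mean_bias_rounded = round_half_up(mean(bias), 1))
}

#' Mean bias of a report
#'
#' @param report A `bias_report`.
#' @param rounded Return the one-decimal table value instead of the
#'   unrounded mean.
#' @return Mean of the per-SaO2 biases, percent.
#' @export
mean_bias <- function(report, rounded = FALSE) {
  attr(report, if (rounded) "mean_bias_rounded" else "mean_bias")
}

#' Ratio between two cohorts' mean biases
#'
#' Darker-cohort mean bias divided by lighter-cohort mean bias, the summary
#' used to compare simulated and clinical disparities. Accepts
#' `bias_report` objects or bare mean-bias numbers.
#'
#' @param report_light,report_dark Reports (or numeric mean biases) for the
#'   lighter and darker cohort.
#' @return `mean_bias_dark / mean_bias_light`.
#' @export
#' @examples
#' cohort_bias_ratio(0.5, 3.3)  # 6.6, clinical-study value
cohort_bias_ratio <- function(report_light, report_dark) {
  mb <- function(x) if (inherits(x, "bias_report")) mean_bias(x) else x
  a <- mb(report_light); b <- mb(report_dark)
  if (a == 0) stop("light-cohort mean bias is zero", call. = FALSE)
  b / a
}

#' Linear correction multiplier at a reference saturation
#'
#' Ratio between the R of the reference (light) curve and the R of another
#' phototype's curve at one reference saturation.
#'
#' @param curve_ref,curve_other Reference and target `calibration_curve`s.
#' @param sao2_ref Reference saturation in percent (default 100).
#' @return A `correction_factor` of kind `"linear_at_reference"`.
#' @export
#' @examples
#' light <- calibration_curve(109, -25.95)
#' dark <- calibration_curve(110.6, -50.31)
#' reference_multiplier(light, dark)  # ~1.65
reference_multiplier <- function(curve_ref, curve_other, sao2_ref = 100) {
  r_ref <- invert_calibration(curve_ref, sao2_ref)
  r_other <- invert_calibration(curve_other, sao2_ref)
  if (r_other == 0) stop("target curve has R = 0 at the reference",
                         call. = FALSE)
  factor <- r_ref / r_other
  structure(list(kind = "linear_at_reference", reference = sao2_ref,
                 profile = tibble::tibble(sao2 = sao2_ref, factor = factor),
                 factor = factor),
            class = "correction_factor")
}

#' Correction-multiplier profile over a saturation grid
#'
#' Per-saturation ratios between the reference and target curves' R values;
#' the applied factor is the arithmetic mean of the profile. Along the
#' oximetry range the profile is not constant (it grows towards high
#' saturation), which is why a single linear multiplier under-corrects dark
#' skin and a mean-of-profile factor is used instead.
#'
#' @param curve_ref,curve_other Reference and target `calibration_curve`s.
#' @param sao2_grid Saturation grid in percent (default 70 to 100 by 5).
#' @return A `correction_factor` of kind `"mean_of_profile"` with the full
#'   per-saturation `profile`.
#' @export
multiplier_profile <- function(curve_ref, curve_other,
                               sao2_grid = seq(70, 100, by = 5)) {
  if (length(sao2_grid) == 0) stop("empty saturation grid", call. = FALSE)
  r_ref <- invert_calibration(curve_ref, sao2_grid)
  r_other <- invert_calibration(curve_other, sao2_grid)
  if (any(r_other == 0)) stop("target curve has R = 0 on the grid",
                              call. = FALSE)
  prof <- tibble::tibble(sao2 = sao2_grid, factor = r_ref / r_other)
  structure(list(kind = "mean_of_profile", reference = sao2_grid,
                 profile = prof, factor = mean(prof$factor)),
            class = "correction_factor")
}

#' @export
print.correction_factor <- function(x, ...) {
  cat(sprintf("<correction_factor> %s: factor %.4g (%d grid point%s)\n",
              x$kind, x$factor, nrow(x$profile),
              if (nrow(x$profile) == 1) "" else "s"))
  invisible(x)
}

#' Apply a correction multiplier to a curve or to points
#'
#' Scaling every R by a factor `f` maps the line `SaO2 = a + b R` exactly to
#' `SaO2 = a + (b / f) R`; for raw points the R column is scaled and the
#' curve refitted.
#'
#' @param x A `calibration_curve`, or a tibble with columns `R` and `sao2`.
#' @param factor A positive multiplier or a `correction_factor`.
#' @return Corrected object of the same type as `x`.
#' @export
apply_multiplier <- function(x, factor) {
  if (inherits(factor, "correction_factor")) factor <- factor$factor
  if (factor <= 0) stop("factor must be positive", call. = FALSE)
  if (inherits(x, "calibration_curve")) {
    return(calibration_curve(x$intercept, x$slope / factor,
                             label = paste0(x$label, "_adjusted"),
                             n_points = x$n_points))
  }
  stopifnot(all(c("R", "sao2") %in% names(x)))
  pts <- x
  pts$R <- pts$R * factor
  fit_calibration(pts, label = "adjusted")
}
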