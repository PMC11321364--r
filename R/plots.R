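#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot calibration curves with their underlying points
#'
#' Scatter of SaO2 against the ratio of ratios per skin phototype with the
#' fitted lines and, optionally, the commercial relation as reference.
#'
#' @param acdc AC/DC table with columns `skin`, `sao2`, `R` (e.g. from
#'   [acdc_table()]); may be `NULL` to plot lines only.
#' @param curves Named list of `calibration_curve` objects.
#' @param commercial Draw the commercial relation as a dashed reference.
#' @return A ggplot.
#' @export
plot_calibration <- function(acdc = NULL, curves = NULL,
                             commercial = TRUE) {
  p <- ggplot2::ggplot()
  if (!is.null(acdc)) {
    p <- p + ggplot2::geom_point(
      data = acdc,
      ggplot2::aes(x = .data$R, y = .data$sao2, colour = .data$skin))
  }
  if (!is.null(curves)) {
    lines <- purrr::imap_dfr(curves, function(cv, nm) {
      tibble::tibble(skin = nm,
                     R = seq(0, 1.6, length.out = 50),
                     sao2 = predict(cv, seq(0, 1.6, length.out = 50)))
    })
    p <- p + ggplot2::geom_line(
      data = lines,
      ggplot2::aes(x = .data$R, y = .data$sao2, colour = .data$skin))
  }
  if (commercial) {
    com <- commercial_curve()
    p <- p + ggplot2::geom_abline(intercept = com$intercept,
                                  slope = com$slope, linetype = "dashed")
  }
  p + ggplot2::coord_cartesian(ylim = c(70, 110)) +
    ggplot2::labs(x = "ratio of ratios R", y = expression(SaO[2] ~ "(%)"),
                  colour = "skin")
}

#' @describeIn bias_report Plot bias against true saturation.
#' @param object A `bias_report`.
#' @param ... Unused.
#' @export
autoplot.bias_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sao2, y = .data$bias)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = mean_bias(object),
                        linetype = "dashed") +
    ggplot2::labs(x = expression(SaO[2] ~ "(%)"),
                  y = expression(SpO[2] - SaO[2] ~ "(%)"))
}

#' @describeIn multiplier_profile Plot the per-saturation multiplier
#'   profile and its mean.
#' @param object A `correction_factor`.
#' @param ... Unused.
#' @export
autoplot.correction_factor <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$sao2, y = .data$factor)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$factor, linetype = "dashed") +
    ggplot2::labs(x = expression(SaO[2] ~ "(%)"),
                  y = "R multiplier (reference / target)")
}

#' @describeIn assemble_tables Plot the fitted calibration curves of a
#'   result.
#' @param object An `experiment_result`.
#' @param ... Unused.
#' @export
autoplot.experiment_result <- function(object, ...) {
  plot_calibration(object$acdc,
                   object$curves %||% object$fitted_curves)
}
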