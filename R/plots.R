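#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.loglog_fit <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$lx, y = .data$ly)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(intercept = g$intercept, slope = g$slope,
                         colour = "steelblue") +
    ggplot2::labs(x = "log10(x)", y = "log10(y)",
                  subtitle = sprintf("slope %.3f, prefactor %.3g, R^2 %.3f",
                                     g$slope, g$prefactor, g$r_squared)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.dive_survey <- function(object, which = c("force", "pressure"), ...) {
  which <- match.arg(which)
  ycol <- if (which == "force") "F_max" else "P"
  ylab <- if (which == "force") "peak impact force (N)" else "impact pressure (Pa)"
  fit <- attr(object, paste0("fit_", which))
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$mass, y = .data[[ycol]],
                                    colour = .data$orientation)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "body mass (kg)", y = ylab) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    g <- glance(fit)
    p <- p + ggplot2::labs(
      subtitle = sprintf("log-log slope %.3f (95%% CI %.3f to %.3f)",
                         g$slope, g$slope_conf_low, g$slope_conf_high))
  }
  p
}

#' Plot the flow field around the moving plate
#'
#' Filled velocity-potential map with streamfunction contours from a
#' [plate_field()] grid; the plate cut shows as the blank band.
#'
#' @param field A tibble from [plate_field()].
#' @return A ggplot object.
#' @export
plot_plate_field <- function(field) {
  stopifnot(is.data.frame(field),
            all(c("x", "y", "phi", "psi") %in% names(field)))
  ggplot2::ggplot(field, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$phi)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$psi),
                          colour = "grey20", linewidth = 0.2,
                          na.rm = TRUE) +
    ggplot2::scale_fill_viridis_c(name = "phi") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
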