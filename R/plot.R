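#' Plot a spectrum
#'
#' @param object A `libs_spectrum`.
#' @param peaks Optional `libs_peaks` tibble; fitted Lorentzian components
#'   and their shared baseline are overlaid on the raw trace.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.libs_spectrum <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$wavelength,
                                    y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Wavelength (nm)", y = "Intensity (AU)")
  if (!is.null(peaks) && nrow(peaks) > 0) {
    win <- attr(peaks, "window") %||% range(object$wavelength)
    base <- attr(peaks, "baseline") %||% 0
    grid <- seq(win[1], win[2], length.out = 400)
    comps <- purrr::pmap_dfr(
      list(peaks$center, peaks$fwhm, peaks$amplitude,
           seq_len(nrow(peaks))),
      function(cc, w, A, id) {
        tibble(wavelength = grid,
               intensity = base + A * (w / 2)^2 /
                 ((grid - cc)^2 + (w / 2)^2),
               component = factor(id))
      })
    p <- p + ggplot2::geom_line(
      data = comps,
      ggplot2::aes(colour = .data$component),
      linetype = "dashed", linewidth = 0.5) +
      ggplot2::labs(colour = "Fit component")
  }
  p
}

#' Plot a calibration curve
#'
#' Calibration points with the fitted OLS line, annotated with the mode and
#' R-squared.
#'
#' @param object A `libs_calibration`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.libs_calibration <- function(object, ...) {
  lab <- sprintf("%s mode: R² = %.4f", object$mode, object$r_squared)
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$concentration, y = .data$response)) +
    ggplot2::geom_point(shape = if (object$mode == "area") 17 else 1,
                        size = 2) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = "dashed") +
    ggplot2::labs(
      x = expression(Concentration ~ (nmol / mm^2)),
      y = if (object$mode == "area") {
        "Normalized peak area (AU nm)"
      } else {
        "Normalized peak intensity (AU)"
      },
      subtitle = lab)
}
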