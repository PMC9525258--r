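#' Element response from fitted peaks
#'
#' Aggregates the matched peaks of one element into a single quantitative
#' response. In `"area"` mode the response is the sum of the analytic areas
#' of every matched line -- every detected photon of the element counts, so
#' the response stays linear in concentration even when self-broadening
#' suppresses peak height. In `"intensity"` mode it is the amplitude of the
#' single strongest matched line, the conventional peak-height readout the
#' area approach is contrasted with.
#'
#' @param peaks A `libs_peaks` tibble (or row-bound tibble of several
#'   windows' fits).
#' @param element Element symbol.
#' @param table Reference line table.
#' @param mode `"area"` or `"intensity"`.
#' @param tol Match tolerance in nm, see [match_lines()].
#' @return A single numeric response (AU nm in area mode, AU in intensity
#'   mode).
#' @export
element_response <- function(peaks, element, table = libs_reference_lines(),
                             mode = c("area", "intensity"), tol = 0.15) {
  mode <- match.arg(mode)
  matches <- match_lines(peaks, table = table, tol = tol)
  matches <- matches[matches$element == element, ]
  if (nrow(matches) == 0L) {
    abort(sprintf("No fitted peak matches a reference line of '%s'.",
                  element),
          class = "libsquant_no_match")
  }
  if (mode == "area") sum(matches$area) else max(matches$amplitude)
}

#' Internal-standard normalization
#'
#' @param analyte Analyte response.
#' @param standard Internal-standard response (> 0).
#' @return `analyte / standard`.
#' @export
normalize_response <- function(analyte, standard) {
  if (any(standard <= 0)) {
    abort("Internal-standard response must be positive.",
          class = "libsquant_invalid_standard")
  }
  analyte / standard
}

#' Build a linear calibration curve
#'
#' Ordinary least squares of response on concentration over the calibration
#' points, the plain linear calibration used to judge the linearity of the
#' area- and intensity-mode readouts.
#'
#' @param points Tibble with columns `concentration` (nmol/mm2) and
#'   `response`; at least 3 points over at least 2 distinct concentrations.
#' @param mode `"area"` or `"intensity"`, recorded on the curve.
#' @param normalized Whether responses were internal-standard normalized.
#' @return An object of class `libs_calibration`: slope, intercept,
#'   `r_squared`, mode, the points, and the underlying `lm` fit. Supports
#'   [tidy()], [glance()], [autoplot()] and [predict_concentration()].
#' @examples
#' pts <- tibble::tibble(concentration = 1:5, response = 2 * (1:5))
#' build_calibration(pts)
#' @export
build_calibration <- function(points, mode = c("area", "intensity"),
                              normalized = TRUE) {
  mode <- match.arg(mode)
  stopifnot(all(c("concentration", "response") %in% names(points)))
  if (nrow(points) < 3L) {
    abort("A calibration needs at least 3 points.",
          class = "libsquant_degenerate_design")
  }
  if (length(unique(points$concentration)) < 2L) {
    abort("A calibration needs at least 2 distinct concentrations.",
          class = "libsquant_degenerate_design")
  }
  if (any(points$concentration < 0) || any(points$response < 0)) {
    abort("Concentrations and responses must be non-negative.",
          class = "libsquant_degenerate_design")
  }
  fit <- lm(response ~ concentration, data = points)
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = exact_safe_summary(fit)$r.squared,
    mode = mode,
    normalized = normalized,
    points = as_tibble(points),
    model = fit), class = "libs_calibration")
}

#' @export
print.libs_calibration <- function(x, ...) {
  cat(sprintf(
    "<libs_calibration> %s mode%s: response = %.6g + %.6g * conc, R^2 = %.6f (%d points)\n",
    x$mode, if (x$normalized) " (normalized)" else "", x$intercept, x$slope,
    x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Invert a calibration curve
#'
#' @param curve A `libs_calibration`.
#' @param response Observed response(s) on the curve's scale.
#' @return Predicted concentration(s), `(response - intercept) / slope`.
#' @export
predict_concentration <- function(curve, response) {
  if (curve$slope == 0) {
    abort("Calibration slope is zero; concentration is undefined.",
          class = "libsquant_degenerate_design")
  }
  (response - curve$intercept) / curve$slope
}

#' Calibrate a simulated or measured spectrum series
#'
#' End-to-end calibration: for each level's spectrum, fits the analyte's
#' reference-line windows (joint Lorentzian multiplets initialized at the
#' table wavelengths) and the internal-standard window, aggregates matched
#' responses per [element_response()], optionally divides by the standard
#' response, and fits the OLS calibration line.
#'
#' @param series A `libs_series` from [simulate_calibration_series()], or
#'   any tibble with `concentration` and a `spectrum` list column.
#' @param analyte Analyte element (default: the series' `analyte`
#'   attribute, else `"K"`).
#' @param standard Internal-standard element (default from the series,
#'   else `"Na"`); `NULL` disables normalization.
#' @param table Reference line table.
#' @param mode `"area"` or `"intensity"`.
#' @param normalize Divide by the standard response?
#' @param standard_window Window (nm) whose standard lines are used for
#'   normalization; default 586--592 nm, the Na D region.
#' @param tol Match tolerance, nm.
#' @return A `libs_calibration` whose points carry `concentration`,
#'   `analyte_response`, `standard_response` and the (possibly normalized)
#'   `response`.
#' @export
calibrate_series <- function(series,
                             analyte = attr(series, "analyte") %||% "K",
                             standard = names(attr(series, "standard")) %||%
                               "Na",
                             table = libs_reference_lines(),
                             mode = c("area", "intensity"),
                             normalize = TRUE,
                             standard_window = c(586, 592),
                             tol = 0.15) {
  mode <- match.arg(mode)
  stopifnot(all(c("concentration", "spectrum") %in% names(series)))
  awin <- element_windows(analyte, table = table)
  rows <- purrr::map2_dfr(series$concentration, series$spectrum,
                          function(conc, spec) {
    apeaks <- fit_element_windows(spec, awin)
    a_resp <- element_response(apeaks, analyte, table = table, mode = mode,
                               tol = tol)
    s_resp <- NA_real_
    if (!is.null(standard) && normalize) {
      s_lines <- table$wavelength[table$element == standard &
                                    table$wavelength >= standard_window[1] &
                                    table$wavelength <= standard_window[2]]
      if (length(s_lines) == 0L) {
        abort(sprintf("No '%s' lines inside the standard window.", standard),
              class = "libsquant_no_lines")
      }
      speaks <- fit_multiplet(spec, window = standard_window,
                              k = length(s_lines), init = s_lines)
      s_resp <- element_response(speaks, standard, table = table,
                                 mode = mode, tol = tol)
    }
    tibble(concentration = conc, analyte_response = a_resp,
           standard_response = s_resp)
  })
  rows$response <- if (normalize) {
    normalize_response(rows$analyte_response, rows$standard_response)
  } else {
    rows$analyte_response
  }
  build_calibration(rows, mode = mode, normalized = normalize)
}

## fit every window of an element_windows() table and bind the peak rows
fit_element_windows <- function(spec, windows) {
  purrr::pmap_dfr(windows, function(element, lo, hi, k, lines) {
    as_tibble(fit_multiplet(spec, window = c(lo, hi), k = k, init = lines))
  })
}

## summary.lm warns on an essentially perfect fit; exact synthetic
## calibrations are legitimate input here, so that warning is muted
exact_safe_summary <- function(fit) {
  withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}
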