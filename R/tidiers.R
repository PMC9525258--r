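#' Tidy a calibration curve
#'
#' @param x A `libs_calibration`.
#' @param ... Unused.
#' @return One row per model term (`(Intercept)`, `concentration`) with
#'   `estimate`, `std.error`, `statistic`, `p.value`.
#' @export
tidy.libs_calibration <- function(x, ...) {
  cf <- exact_safe_summary(x$model)$coefficients
  tibble(term = rownames(cf),
         estimate = cf[, "Estimate"],
         std.error = cf[, "Std. Error"],
         statistic = cf[, "t value"],
         p.value = cf[, "Pr(>|t|)"])
}

#' Glance at a calibration curve
#'
#' @param x A `libs_calibration`.
#' @param ... Unused.
#' @return One-row tibble: `r.squared`, `adj.r.squared`, `sigma`, `slope`,
#'   `intercept`, `mode`, `normalized`, `nobs`.
#' @export
glance.libs_calibration <- function(x, ...) {
  sm <- exact_safe_summary(x$model)
  tibble(r.squared = sm$r.squared,
         adj.r.squared = sm$adj.r.squared,
         sigma = sm$sigma,
         slope = x$slope,
         intercept = x$intercept,
         mode = x$mode,
         normalized = x$normalized,
         nobs = nrow(x$points))
}

#' Tidy a Na/K ratio result
#'
#' @param x A `libs_ratio`.
#' @param ... Unused.
#' @return The per-shot tibble (`shot`, `na_area`, `k_area`, `ratio`).
#' @export
tidy.libs_ratio <- function(x, ...) x$per_shot

#' Glance at a Na/K ratio result
#'
#' @param x A `libs_ratio`.
#' @param ... Unused.
#' @return One-row tibble: `ratio`, `sd`, `shots_used`, `k_correction`,
#'   `single_shot`.
#' @export
glance.libs_ratio <- function(x, ...) {
  tibble(ratio = x$ratio, sd = x$sd, shots_used = x$shots_used,
         k_correction = x$k_correction, single_shot = x$single_shot)
}
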