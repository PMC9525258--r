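#' Corrected Na/K ratio over single-shot spectra
#'
#' For each of the first `n_shots` single-shot spectra, fits the Na line
#' windows (589 and 819 nm regions) and the K resonance doublet window,
#' sums the analytic areas per element, and forms
#' `ratio = sum(Na areas) / (k_correction * sum(K areas))`. The per-shot
#' ratios' mean and standard deviation are reported; because both elements
#' share each shot's plasma, pulse-to-pulse intensity variation cancels in
#' the ratio.
#'
#' The default `k_correction = 1.719` is an instrument-response equalizer:
#' multiplying the K area by it makes equal molar amounts of Na and K yield
#' equal corrected areas on the reference instrument (and on this package's
#' default simulator, whose sensitivities encode the same asymmetry). It is
#' an empirical constant for the default Na/K line set and must be
#' re-derived for any other instrument or line selection, never silently
#' reused.
#'
#' @param shots List of single-shot `libs_spectrum` objects (at least
#'   `n_shots`).
#' @param table Reference line table.
#' @param k_correction Multiplicative correction applied to the summed K
#'   area before ratioing.
#' @param n_shots Number of leading shots analyzed (default 4).
#' @param tol Match tolerance, nm.
#' @return An object of class `libs_ratio`: `ratio` (mean over shots), `sd`
#'   (0 with a `single_shot` flag when `n_shots` is 1), `per_shot` tibble
#'   (`shot`, `na_area`, `k_area`, `ratio`), `k_correction`, `shots_used`.
#'   Supports [tidy()] and [glance()].
#' @export
na_k_ratio <- function(shots, table = libs_reference_lines(),
                       k_correction = 1.719, n_shots = 4, tol = 0.15) {
  stopifnot(k_correction > 0, n_shots >= 1)
  if (length(shots) < n_shots) {
    abort(sprintf("Need at least %d shot spectra; got %d.", n_shots,
                  length(shots)),
          class = "libsquant_insufficient_shots")
  }
  na_win <- element_windows("Na", table = table)
  k_win <- element_windows("K", table = table)
  per_shot <- purrr::map_dfr(seq_len(n_shots), function(i) {
    s <- shots[[i]]
    na_peaks <- fit_element_windows(s, na_win)
    k_peaks <- fit_element_windows(s, k_win)
    na_area <- element_response(na_peaks, "Na", table = table,
                                mode = "area", tol = tol)
    k_area <- element_response(k_peaks, "K", table = table,
                               mode = "area", tol = tol)
    if (k_area <= 0) {
      abort(sprintf("K response is zero in shot %d; ratio undefined.", i),
            class = "libsquant_zero_response")
    }
    tibble(shot = i, na_area = na_area, k_area = k_area,
           ratio = na_area / (k_correction * k_area))
  })
  structure(list(
    ratio = mean(per_shot$ratio),
    sd = if (n_shots == 1L) 0 else sd(per_shot$ratio),
    single_shot = n_shots == 1L,
    per_shot = per_shot,
    k_correction = k_correction,
    shots_used = n_shots), class = "libs_ratio")
}

#' @export
print.libs_ratio <- function(x, ...) {
  cat(sprintf(
    "<libs_ratio> Na/K = %.4g +/- %.4g over %d shot(s) (K area corrected by %.4g)%s\n",
    x$ratio, x$sd, x$shots_used, x$k_correction,
    if (x$single_shot) " [single shot]" else ""))
  invisible(x)
}
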