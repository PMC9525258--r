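#' Match fitted peaks against a reference line table
#'
#' Greedy nearest-wavelength assignment: all (peak, line) pairs within
#' `tol` nm are ranked by ascending |delta| (ties broken toward the stronger
#' line, then the shorter wavelength) and accepted one by one, so each peak
#' claims at most one line and each line at most one peak, and a peak wanted
#' by two elements goes to the closer line. Each element's score is the
#' summed relative strength of its matched lines divided by the summed
#' strength of all its table lines inside `range`, so a full pattern match
#' scores 1.
#'
#' @param peaks A `libs_peaks` tibble (or any tibble with `center`,
#'   `amplitude`, `area` columns).
#' @param table Reference line table, see [read_line_table()].
#' @param tol Match tolerance, nm (default 0.15, half the default base
#'   FWHM).
#' @param range Spectral range (nm) over which line coverage is scored.
#' @return A tibble with one row per matched pair: `element`, `score`,
#'   `center`, `wavelength`, `species`, `delta`, `rel_strength`, plus the
#'   peak's `amplitude` and `area`; elements sorted by descending score,
#'   zero-match elements omitted. Empty input gives an empty tibble.
#' @export
match_lines <- function(peaks, table = libs_reference_lines(), tol = 0.15,
                        range = c(127, 868)) {
  stopifnot(tol > 0)
  empty <- tibble(element = character(), score = numeric(),
                  center = numeric(), wavelength = numeric(),
                  species = character(), delta = numeric(),
                  rel_strength = numeric(), amplitude = numeric(),
                  area = numeric())
  if (nrow(peaks) == 0L || nrow(table) == 0L) return(empty)
  peaks <- dplyr::arrange(as_tibble(peaks), .data$center)
  pairs <- tidyr::expand_grid(peak_id = seq_len(nrow(peaks)),
                              line_id = seq_len(nrow(table)))
  pairs$delta <- abs(peaks$center[pairs$peak_id] -
                       table$wavelength[pairs$line_id])
  pairs <- pairs[pairs$delta <= tol, ]
  if (nrow(pairs) == 0L) return(empty)
  pairs <- pairs[order(pairs$delta, -table$rel_strength[pairs$line_id],
                       table$wavelength[pairs$line_id]), ]
  used_peak <- logical(nrow(peaks))
  used_line <- logical(nrow(table))
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    p <- pairs$peak_id[i]
    l <- pairs$line_id[i]
    if (!used_peak[p] && !used_line[l]) {
      used_peak[p] <- TRUE
      used_line[l] <- TRUE
      keep[i] <- TRUE
    }
  }
  pairs <- pairs[keep, ]
  out <- tibble(
    element = table$element[pairs$line_id],
    center = peaks$center[pairs$peak_id],
    wavelength = table$wavelength[pairs$line_id],
    species = table$species[pairs$line_id],
    delta = pairs$delta,
    rel_strength = table$rel_strength[pairs$line_id],
    amplitude = peaks$amplitude[pairs$peak_id],
    area = peaks$area[pairs$peak_id])
  in_range <- table[table$wavelength >= range[1] &
                      table$wavelength <= range[2], ]
  totals <- dplyr::summarise(dplyr::group_by(in_range, .data$element),
                             total_strength = sum(.data$rel_strength),
                             .groups = "drop")
  out <- dplyr::left_join(out, totals, by = "element")
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$element),
    score = sum(.data$rel_strength) / .data$total_strength[1])
  out <- dplyr::ungroup(out)
  out$total_strength <- NULL
  dplyr::arrange(out, dplyr::desc(.data$score), .data$element,
                 .data$wavelength)
}

#' Cosine similarity between a spectrum and a reference spectrum
#'
#' Interpolates the reference onto the sample grid over the overlapping
#' wavelength range, subtracts each spectrum's median (a robust stand-in for
#' its flat baseline) and returns the cosine similarity of the residual
#' patterns. Identical patterns score 1; a flat spectrum scores 0 by
#' convention.
#'
#' @param s,ref `libs_spectrum` objects with overlapping ranges.
#' @return Similarity in `[-1, 1]` (non-negative for emission-only spectra).
#' @export
compare_reference <- function(s, ref) {
  lo <- max(min(s$wavelength), min(ref$wavelength))
  hi <- min(max(s$wavelength), max(ref$wavelength))
  if (lo >= hi) {
    abort("Spectra do not share a wavelength range.",
          class = "libsquant_disjoint_ranges")
  }
  sel <- s$wavelength >= lo & s$wavelength <= hi
  x <- s$wavelength[sel]
  a <- s$intensity[sel]
  b <- approx(ref$wavelength, ref$intensity, xout = x, rule = 2)$y
  a <- a - median(a)
  b <- b - median(b)
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
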