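#' Read a reference emission-line table
#'
#' A line table is a CSV with header `element,species,wavelength_nm,
#' rel_strength` (leading `#` comment lines allowed): one row per reference
#' transition, with a unitless relative emissivity. Duplicate
#' (element, species, wavelength) rows and non-positive strengths or
#' wavelengths are rejected.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `element`, `species`, `wavelength` (nm) and
#'   `rel_strength`.
#' @export
read_line_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Line table not found: %s", path),
          class = "libsquant_io_error")
  }
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  required <- c("element", "species", "wavelength_nm", "rel_strength")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(sprintf("Line table is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "libsquant_io_error")
  }
  tab <- dplyr::transmute(tab,
    element = as.character(.data$element),
    species = as.character(.data$species),
    wavelength = as.numeric(.data$wavelength_nm),
    rel_strength = as.numeric(.data$rel_strength))
  if (nrow(tab) == 0L) return(tab)
  if (any(tab$wavelength <= 0)) {
    abort("Line wavelengths must be positive.", class = "libsquant_io_error")
  }
  if (any(tab$rel_strength <= 0)) {
    abort("Relative strengths must be positive.", class = "libsquant_io_error")
  }
  key <- paste(tab$element, tab$species, tab$wavelength)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(sprintf("Duplicate line table entry: %s", dup),
          class = "libsquant_io_error")
  }
  tab
}

#' Packaged reference line table
#'
#' The default emission-line table shipped with the package. The Na
#' (589.18, 819.22 nm) and K (766.39, 769.98 nm) resonance wavelengths are
#' the published values this pipeline quantifies; Ca, Ba and Sr rows are
#' synthetic fixture entries for simulator and identification examples, and
#' all relative strengths are nominal instrument-relative values.
#'
#' @return A tibble in the format of [read_line_table()].
#' @examples
#' libs_reference_lines()
#' @export
libs_reference_lines <- function() {
  read_line_table(system.file("extdata", "reference_lines.csv",
                              package = "libsquant", mustWork = TRUE))
}

#' Default fit windows for the quantified lines
#'
#' Fit windows (nm) used throughout: the K resonance doublet window and the
#' two Na windows. The 586--592 nm window isolates the Na D region used for
#' internal-standard normalization.
#'
#' @return Named list of length-2 numeric ranges in nm.
#' @export
libs_windows <- function() {
  list(K = c(763, 773), Na589 = c(586, 592), Na819 = c(816, 822))
}

#' Derive fit windows for an element from a line table
#'
#' Groups an element's reference wavelengths into windows of
#' `2 * half_width` nm, merging windows whose lines lie closer than
#' `2 * half_width`, and counts the lines per window (the number of
#' Lorentzian components to fit jointly).
#'
#' @param element Element symbol.
#' @param table Line table tibble (default: packaged table).
#' @param half_width Half window width in nm.
#' @param range Restrict to lines inside this wavelength range (nm).
#' @return A tibble with columns `element`, `lo`, `hi`, `k` and a list
#'   column `lines` of the wavelengths in each window.
#' @export
element_windows <- function(element, table = libs_reference_lines(),
                            half_width = 5, range = c(127, 868)) {
  wl <- sort(table$wavelength[table$element == element &
                              table$wavelength >= range[1] &
                              table$wavelength <= range[2]])
  if (length(wl) == 0L) {
    abort(sprintf("No reference lines for element '%s' in range.", element),
          class = "libsquant_no_lines")
  }
  grp <- cumsum(c(1, diff(wl) > 2 * half_width))
  purrr::map_dfr(split(wl, grp), function(w) {
    tibble(element = element,
           lo = max(range[1], min(w) - half_width),
           hi = min(range[2], max(w) + half_width),
           k = length(w), lines = list(w))
  })
}
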