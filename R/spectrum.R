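#' Construct a LIBS emission spectrum
#'
#' A spectrum is a tibble with columns `wavelength` (nm, strictly increasing)
#' and `intensity` (arbitrary detector units, non-negative), carrying
#' free-form shot metadata and the declared instrument wavelength range as
#' attributes. It is the exchange object passed between the simulator, the
#' peak fitter and the quantification helpers.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing.
#' @param intensity Numeric vector of intensities in AU, same length,
#'   non-negative.
#' @param meta Named list of metadata (e.g. `sample_id`, `spot`,
#'   `shots_accumulated`).
#' @param range Declared instrument wavelength range in nm; all wavelengths
#'   must fall inside it. Defaults to the 127--868 nm span of a broadband
#'   LIBS spectrometer.
#'
#' @return A tibble of class `libs_spectrum` with columns `wavelength` and
#'   `intensity` and attributes `meta` and `instrument_range`.
#' @examples
#' s <- libs_spectrum(c(766.0, 766.1), c(10, 12))
#' spectrum_meta(s)
#' @export
libs_spectrum <- function(wavelength, intensity, meta = list(),
                          range = c(127, 868)) {
  wavelength <- as.numeric(wavelength)
  intensity <- as.numeric(intensity)
  if (length(wavelength) != length(intensity)) {
    abort("`wavelength` and `intensity` must have the same length.",
          class = "libsquant_invalid_spectrum")
  }
  if (anyNA(wavelength) || anyNA(intensity)) {
    abort("Spectrum values must not contain NA.",
          class = "libsquant_invalid_spectrum")
  }
  if (length(wavelength) > 1L) {
    bad <- which(diff(wavelength) <= 0)
    if (length(bad) > 0L) {
      abort(sprintf(
        "Wavelength grid must be strictly increasing; violation at row %d (%.6g nm after %.6g nm).",
        bad[1] + 1L, wavelength[bad[1] + 1L], wavelength[bad[1]]),
        class = "libsquant_invalid_spectrum")
    }
  }
  if (any(intensity < 0)) {
    abort("Intensities must be non-negative.",
          class = "libsquant_invalid_spectrum")
  }
  if (length(wavelength) > 0L &&
      (min(wavelength) < range[1] || max(wavelength) > range[2])) {
    abort(sprintf(
      "Wavelengths must lie within the declared instrument range [%g, %g] nm.",
      range[1], range[2]),
      class = "libsquant_invalid_spectrum")
  }
  out <- tibble(wavelength = wavelength, intensity = intensity)
  attr(out, "meta") <- meta
  attr(out, "instrument_range") <- as.numeric(range)
  class(out) <- c("libs_spectrum", class(out))
  out
}

#' Spectrum metadata
#'
#' @param s A `libs_spectrum`.
#' @return The named metadata list stored on the spectrum.
#' @export
spectrum_meta <- function(s) {
  attr(s, "meta") %||% list()
}

#' @export
print.libs_spectrum <- function(x, ...) {
  meta <- spectrum_meta(x)
  rng <- attr(x, "instrument_range")
  cat(sprintf("<libs_spectrum> %d points", nrow(x)))
  if (nrow(x) > 0) {
    cat(sprintf(", %.2f-%.2f nm", min(x$wavelength), max(x$wavelength)))
  }
  if (!is.null(rng)) cat(sprintf(" (instrument %g-%g nm)", rng[1], rng[2]))
  cat("\n")
  if (length(meta) > 0) {
    cat("meta:", paste(names(meta), unlist(lapply(meta, format)),
                       sep = "=", collapse = " "), "\n")
  }
  NextMethod()
}

#' Read a spectrum from delimited text
#'
#' Reads the package's plain-text spectrum dialect: optional leading comment
#' lines starting with `#` (parsed as `key: value` metadata when they contain
#' a colon), followed by two numeric columns (wavelength nm, intensity AU)
#' separated by a comma or whitespace (auto-detected).
#'
#' @param path Path to the spectrum file.
#' @param range Declared instrument range passed to [libs_spectrum()].
#' @return A `libs_spectrum`.
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path, range = c(127, 868)) {
  if (!file.exists(path)) {
    abort(sprintf("Spectrum file not found: %s", path),
          class = "libsquant_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  is_blank <- grepl("^\\s*$", lines)
  meta <- parse_meta_comments(lines[is_comment])
  data_lines <- lines[!is_comment & !is_blank]
  data_rows <- which(!is_comment & !is_blank)
  if (length(data_lines) == 0L) {
    return(libs_spectrum(numeric(), numeric(), meta = meta, range = range))
  }
  sep_comma <- grepl(",", data_lines[1], fixed = TRUE)
  parts <- if (sep_comma) {
    strsplit(data_lines, "\\s*,\\s*")
  } else {
    strsplit(trimws(data_lines), "\\s+")
  }
  n_fields <- lengths(parts)
  if (any(n_fields < 2L)) {
    bad <- which(n_fields < 2L)[1]
    abort(sprintf("Row %d of %s does not have two columns.",
                  data_rows[bad], path),
          class = "libsquant_io_error")
  }
  wl <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  it <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(wl) || anyNA(it)) {
    bad <- which(is.na(wl) | is.na(it))[1]
    abort(sprintf("Non-numeric value at row %d of %s.", data_rows[bad], path),
          class = "libsquant_io_error")
  }
  if (length(wl) > 1L) {
    bad <- which(diff(wl) <= 0)
    if (length(bad) > 0L) {
      abort(sprintf(
        "Wavelengths out of order at row %d of %s (%.6g nm after %.6g nm).",
        data_rows[bad[1] + 1L], path, wl[bad[1] + 1L], wl[bad[1]]),
        class = "libsquant_io_error")
    }
  }
  libs_spectrum(wl, it, meta = meta, range = range)
}

parse_meta_comments <- function(comment_lines) {
  meta <- list()
  for (ln in comment_lines) {
    body <- sub("^\\s*#\\s*", "", ln)
    if (grepl(":", body, fixed = TRUE)) {
      key <- trimws(sub(":.*$", "", body))
      val <- trimws(sub("^[^:]*:", "", body))
      if (nzchar(key)) {
        num <- suppressWarnings(as.numeric(val))
        meta[[key]] <- if (!is.na(num) && grepl("^[-+0-9.eE]+$", val)) num else val
      }
    }
  }
  if (!is.null(meta$shots_accumulated)) {
    meta$shots_accumulated <- as.integer(meta$shots_accumulated)
  }
  meta
}

#' Write a spectrum to delimited text
#'
#' Writes metadata as `# key: value` comment lines followed by two
#' comma-separated numeric columns at full precision, so that
#' `read_spectrum(write_spectrum(s, path))` round-trips losslessly.
#'
#' @param s A `libs_spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  meta <- spectrum_meta(s)
  header <- character()
  if (length(meta) > 0) {
    vals <- vapply(meta, function(v) {
      if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
    }, "")
    header <- sprintf("# %s: %s", names(meta), vals)
  }
  body <- sprintf("%.17g,%.17g", s$wavelength, s$intensity)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Accumulate laser shots into one spectrum
#'
#' Element-wise sum of the first `n` single-shot spectra on a shared
#' wavelength grid, mirroring on-detector accumulation of successive laser
#' pulses. The result's `shots_accumulated` metadata is set to `n`.
#'
#' @param spectra List of `libs_spectrum` objects on identical grids.
#' @param n Number of leading spectra to accumulate (default: all).
#' @return A `libs_spectrum` with summed intensities.
#' @export
accumulate_shots <- function(spectra, n = length(spectra)) {
  stopifnot(length(spectra) >= 1L)
  n <- as.integer(n)
  if (n < 1L || n > length(spectra)) {
    abort(sprintf("`n` must be between 1 and %d.", length(spectra)),
          class = "libsquant_invalid_spectrum")
  }
  grid <- spectra[[1]]$wavelength
  for (i in seq_len(n)) {
    if (!isTRUE(all.equal(spectra[[i]]$wavelength, grid, tolerance = 0))) {
      abort(sprintf("Spectrum %d is not on the same wavelength grid.", i),
            class = "libsquant_invalid_spectrum")
    }
  }
  total <- Reduce(`+`, lapply(spectra[seq_len(n)], function(s) s$intensity))
  meta <- spectrum_meta(spectra[[1]])
  meta$shots_accumulated <- n
  libs_spectrum(grid, total, meta = meta,
                range = attr(spectra[[1]], "instrument_range") %||% c(127, 868))
}
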