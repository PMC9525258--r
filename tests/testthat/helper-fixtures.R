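# Shared fixtures, built in code at test time.

# Direct Lorentzian evaluation, independent of the package's fit path:
# the oracle against which fitted parameters and analytic areas are checked.
lorentz <- function(x, center, fwhm, amplitude, baseline = 0) {
  hw <- fwhm / 2
  baseline + amplitude * hw^2 / ((x - center)^2 + hw^2)
}

# Spectrum holding exact Lorentzians on a regular grid (no simulator, no
# noise) for peak-fit oracle tests.
lorentz_spectrum <- function(centers, fwhms, amplitudes, baseline = 0,
                             window = NULL, step = 0.05) {
  if (is.null(window)) {
    window <- c(min(centers) - 8, max(centers) + 8)
  }
  x <- seq(window[1], window[2], by = step)
  y <- rep(baseline, length(x))
  for (i in seq_along(centers)) {
    y <- y + lorentz(x, centers[i], fwhms[i], amplitudes[i])
  }
  libs_spectrum(x, pmax(y, 0), range = c(127, 868))
}

# Lazily built, cached default calibration series (shared by several tests
# so the simulation cost is paid once per run).
.series_cache <- new.env(parent = emptyenv())
cached_default_series <- function(seed = 1) {
  key <- paste0("seed_", seed)
  if (is.null(.series_cache[[key]])) {
    .series_cache[[key]] <- simulate_calibration_series(seed = seed)
  }
  .series_cache[[key]]
}

scale_spectrum <- function(s, factor) {
  libs_spectrum(s$wavelength, s$intensity * factor,
                meta = spectrum_meta(s),
                range = attr(s, "instrument_range"))
}
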