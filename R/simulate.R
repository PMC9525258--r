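#' Line models for the forward simulator
#'
#' A line model attaches the physics of one emission line to a reference
#' transition: its zero-concentration FWHM `w0` (nm), its Stark
#' self-broadening coefficient `beta` (per nmol/mm2) and its sensitivity
#' `sensitivity` (integrated area in AU nm produced per nmol/mm2 at unit
#' relative strength). The simulated line is a Lorentzian whose FWHM grows
#' linearly with concentration, `w = w0 (1 + beta c)`, while its integrated
#' area stays exactly `sensitivity * c * rel_strength`: self-broadening
#' redistributes photons in wavelength but loses none, so peak height drops
#' as width grows.
#'
#' @param element Element symbol.
#' @param wavelength Line center, nm.
#' @param species Spectroscopic species label (default `"I"`, neutral atom).
#' @param rel_strength Relative emissivity of the line within its element.
#' @param w0 Base FWHM at zero concentration, nm.
#' @param beta Self-broadening coefficient, per nmol/mm2.
#' @param sensitivity Area response, AU nm per nmol/mm2.
#' @return A one-row tibble; bind rows to build a line-model collection.
#' @export
line_model <- function(element, wavelength, species = "I", rel_strength = 1,
                       w0 = 0.30, beta = 0.02, sensitivity = 100) {
  stopifnot(w0 > 0, beta >= 0, sensitivity > 0, rel_strength > 0,
            wavelength > 0)
  tibble(element = element, species = species, wavelength = wavelength,
         rel_strength = rel_strength, w0 = w0, beta = beta,
         sensitivity = sensitivity)
}

#' Default per-element area sensitivities
#'
#' Element-wise sensitivities (AU nm per nmol/mm2 at unit relative strength)
#' of the default simulated instrument. The Na value is set so that equal
#' molar loadings of Na and K yield summed line areas in the ratio
#' 1.719 : 1 -- the response asymmetry that the default K-area correction
#' factor of [na_k_ratio()] compensates, so that after correction the same
#' amounts of Na and K give the same peak area.
#'
#' @return Named numeric vector.
#' @export
default_sensitivities <- function() {
  ## S_Na * sum(rel_Na = 1.25) = 1.719 * S_K * sum(rel_K = 1.5)
  c(Na = 206.28, K = 100, Ca = 100, Ba = 100, Sr = 100)
}

#' Build line models from a reference table
#'
#' @param elements Elements to include (default: all in `table`).
#' @param table Reference line table, see [read_line_table()].
#' @param w0,beta Base FWHM (nm) and broadening coefficient (per nmol/mm2)
#'   applied to every line.
#' @param sensitivities Named per-element sensitivities; elements absent from
#'   the vector get 100 AU nm per nmol/mm2.
#' @return A line-model tibble, one row per line.
#' @export
default_line_models <- function(elements = NULL,
                                table = libs_reference_lines(),
                                w0 = 0.30, beta = 0.02,
                                sensitivities = default_sensitivities()) {
  if (!is.null(elements)) table <- table[table$element %in% elements, ]
  sens <- unname(sensitivities[table$element])
  sens[is.na(sens)] <- 100
  dplyr::mutate(table, w0 = w0, beta = beta, sensitivity = sens)
}

#' Instrument model
#'
#' @param range Spectrometer wavelength range, nm.
#' @param step Grid step, nm. The 0.05 nm default resolves the 0.3 nm base
#'   FWHM with six points per width.
#' @param baseline Constant detector baseline, AU.
#' @return A list of class `libs_instrument`.
#' @export
instrument_model <- function(range = c(127, 868), step = 0.05, baseline = 10) {
  stopifnot(range[1] < range[2], step > 0, baseline >= 0)
  structure(list(range = as.numeric(range), step = step, baseline = baseline),
            class = "libs_instrument")
}

#' Noise model
#'
#' Per-shot noise: the noiseless signal is scaled by a unit-mean lognormal
#' shot factor (`shot_sd` fractional sd, emulating pulse-to-pulse energy
#' variation), perturbed by per-pixel multiplicative noise
#' (`multiplicative_sd` fractional) and, after adding the baseline, by
#' additive Gaussian detector noise (`additive_sd` AU); negative values are
#' clipped to zero.
#'
#' @param additive_sd Additive noise sd, AU.
#' @param multiplicative_sd Per-pixel fractional noise sd.
#' @param shot_sd Fractional sd of the lognormal per-shot factor.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `libs_noise`.
#' @export
noise_model <- function(additive_sd = 0.5, multiplicative_sd = 0.01,
                        shot_sd = 0.05, seed = NULL) {
  stopifnot(additive_sd >= 0, multiplicative_sd >= 0, shot_sd >= 0)
  structure(list(additive_sd = additive_sd,
                 multiplicative_sd = multiplicative_sd,
                 shot_sd = shot_sd, seed = seed),
            class = "libs_noise")
}

#' Noise-free noise model
#' @return A `libs_noise` with all standard deviations zero.
#' @export
no_noise <- function() noise_model(0, 0, 0, seed = NULL)

#' Noiseless Lorentzian line profile
#'
#' Evaluates one line model at concentration `conc` on a wavelength grid:
#' a Lorentzian with FWHM `w = w0 (1 + beta * conc)` and analytic area
#' `sensitivity * conc * rel_strength`, hence peak amplitude
#' `2 area / (pi w)`.
#'
#' @param line One-row line-model tibble (see [line_model()]).
#' @param conc Concentration, nmol/mm2 (must be >= 0).
#' @param grid Wavelength grid, nm.
#' @return Numeric intensity vector, AU.
#' @export
line_profile <- function(line, conc, grid) {
  if (conc < 0) {
    abort("Concentration must be non-negative.",
          class = "libsquant_invalid_concentration")
  }
  w <- line$w0 * (1 + line$beta * conc)
  area <- line$sensitivity * conc * line$rel_strength
  amp <- 2 * area / (pi * w)
  hw <- w / 2
  amp * hw^2 / ((grid - line$wavelength)^2 + hw^2)
}

#' Simulate LIBS shot spectra
#'
#' Forward model: for each laser shot, the sum of the Lorentzian line
#' profiles of every element in the composition (width and height governed by
#' the Stark self-broadening law of [line_model()]) is scaled by a lognormal
#' shot factor, perturbed per the noise model, offset by the instrument
#' baseline and clipped at zero.
#'
#' @param composition Named numeric vector of concentrations, nmol/mm2
#'   (names are element symbols).
#' @param lines Line-model tibble covering every element in `composition`.
#' @param instrument An [instrument_model()].
#' @param noise A [noise_model()].
#' @param n_shots Number of single-shot spectra to simulate.
#' @param seed Integer seed (default: the noise model's); identical inputs
#'   and seed give bit-identical output.
#' @return A list of `n_shots` single-shot `libs_spectrum` objects.
#' @examples
#' shots <- simulate_spectrum(c(K = 50, Na = 10), seed = 1)
#' @export
simulate_spectrum <- function(composition,
                              lines = default_line_models(names(composition)),
                              instrument = instrument_model(),
                              noise = noise_model(),
                              n_shots = 1, seed = noise$seed) {
  stopifnot(is.numeric(composition), !is.null(names(composition)))
  if (any(composition < 0)) {
    abort("Concentrations must be non-negative.",
          class = "libsquant_invalid_concentration")
  }
  absent <- setdiff(names(composition), unique(lines$element))
  if (length(absent) > 0) {
    abort(sprintf("No line model for element(s): %s",
                  paste(absent, collapse = ", ")),
          class = "libsquant_no_lines")
  }
  grid <- seq(instrument$range[1], instrument$range[2], by = instrument$step)
  signal <- numeric(length(grid))
  for (i in seq_len(nrow(lines))) {
    el <- lines$element[i]
    if (el %in% names(composition) && composition[[el]] > 0) {
      signal <- signal + line_profile(lines[i, ], composition[[el]], grid)
    }
  }
  draw <- function() {
    lapply(seq_len(n_shots), function(shot) {
      sf <- if (noise$shot_sd > 0) {
        sdlog <- noise$shot_sd
        exp(rnorm(1, mean = -sdlog^2 / 2, sd = sdlog))
      } else 1
      y <- signal * sf
      if (noise$multiplicative_sd > 0) {
        y <- y * (1 + rnorm(length(y), 0, noise$multiplicative_sd))
      }
      y <- y + instrument$baseline
      if (noise$additive_sd > 0) {
        y <- y + rnorm(length(y), 0, noise$additive_sd)
      }
      libs_spectrum(grid, pmax(y, 0),
                    meta = list(shot = shot, shots_accumulated = 1L,
                                shot_factor = sf),
                    range = instrument$range)
    })
  }
  if (!is.null(seed)) withr::with_seed(seed, draw()) else draw()
}

#' Default calibration levels
#'
#' Nine log-spaced surface loadings spanning 1 to 144 nmol/mm2, the design
#' of the KCl calibration series on filter paper.
#'
#' @return Numeric vector of length 9.
#' @export
calibration_levels <- function() {
  exp(seq(log(1), log(144), length.out = 9))
}

#' Simulate an internal-standard calibration series
#'
#' One multi-shot recording per analyte level, each spiked with a fixed
#' amount of the internal standard (by default Na, emulating a fixed NaCl
#' spike in a KCl dilution series). Shots are accumulated on-detector into
#' one spectrum per level.
#'
#' @param element Analyte element symbol.
#' @param levels Analyte concentrations, nmol/mm2 (all >= 0).
#' @param standard Named length-1 numeric: internal-standard element and its
#'   fixed concentration.
#' @param lines,instrument,noise Forward-model components; defaults as in
#'   [simulate_spectrum()].
#' @param n_shots Shots accumulated per level (default 2).
#' @param seed Integer master seed; level `i` uses `seed + i`.
#' @return A tibble of class `libs_series` with columns `concentration` and
#'   list column `spectrum` (accumulated `libs_spectrum` per level);
#'   attributes `analyte` and `standard`.
#' @export
simulate_calibration_series <- function(element = "K",
                                        levels = calibration_levels(),
                                        standard = c(Na = 10),
                                        lines = default_line_models(
                                          c(element, names(standard))),
                                        instrument = instrument_model(),
                                        noise = noise_model(),
                                        n_shots = 2, seed = 1) {
  stopifnot(length(levels) >= 1, length(standard) == 1,
            !is.null(names(standard)))
  if (any(levels < 0)) {
    abort("Calibration levels must be non-negative.",
          class = "libsquant_invalid_concentration")
  }
  rows <- purrr::imap(levels, function(lv, i) {
    comp <- setNames(c(lv, unname(standard)), c(element, names(standard)))
    shots <- simulate_spectrum(comp, lines = lines, instrument = instrument,
                               noise = noise, n_shots = n_shots,
                               seed = if (is.null(seed)) NULL else seed + i)
    acc <- accumulate_shots(shots, n_shots)
    meta <- spectrum_meta(acc)
    meta$sample_id <- sprintf("%s_level_%02d", element, i)
    meta$concentration <- lv
    attr(acc, "meta") <- meta
    tibble(concentration = lv, spectrum = list(acc))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "analyte") <- element
  attr(out, "standard") <- standard
  class(out) <- c("libs_series", class(out))
  out
}
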