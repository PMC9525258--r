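test_that("line_profile conserves photons and obeys the broadening law", {
  ln <- line_model("K", 766.39, rel_strength = 1, w0 = 0.30, beta = 0.02,
                   sensitivity = 100)
  grid <- seq(766.39 - 180, 766.39 + 180, by = 0.02)

  expect_equal(line_profile(ln, 0, grid), rep(0, length(grid)))
  expect_error(line_profile(ln, -1, grid),
               class = "libsquant_invalid_concentration")

  # quadrature of the noiseless profile reproduces the analytic area
  for (conc in c(1, 12, 144)) {
    y <- line_profile(ln, conc, grid)
    expect_equal(pracma::trapz(grid, y), 100 * conc, tolerance = 5e-3)
  }

  # width up, height down: the low/high-concentration overlay
  w1 <- 0.30 * (1 + 0.02 * 1)
  w144 <- 0.30 * (1 + 0.02 * 144)
  expect_equal(w144 / w1, (1 + 144 * 0.02) / (1 + 0.02))
  amp <- function(conc) max(line_profile(ln, conc, grid))
  expect_gt(w144 / w1, 1)
  expect_lt(amp(144) / amp(1), 144)
})

test_that("area is invariant in beta while peak height strictly decreases", {
  grid <- seq(766.39 - 180, 766.39 + 180, by = 0.02)
  betas <- seq(0, 0.05, length.out = 6)
  conc <- 50
  areas <- heights <- numeric(length(betas))
  for (i in seq_along(betas)) {
    ln <- line_model("K", 766.39, w0 = 0.30, beta = betas[i],
                     sensitivity = 100)
    y <- line_profile(ln, conc, grid)
    areas[i] <- pracma::trapz(grid, y)
    heights[i] <- max(y)
  }
  expect_lt(max(abs(areas - areas[1])) / areas[1], 5e-3)
  expect_true(all(diff(heights) < 0))
})

test_that("amplitude is increasing and concave in concentration, FWHM linear", {
  ln <- line_model("K", 766.39, w0 = 0.30, beta = 0.02, sensitivity = 100)
  conc <- seq(1, 144, length.out = 30)
  amp <- 2 * 100 * conc / (pi * 0.30 * (1 + 0.02 * conc))
  expect_true(all(diff(amp) > 0))
  expect_true(all(diff(diff(amp)) < 0))
  fwhm <- 0.30 * (1 + 0.02 * conc)
  expect_lt(max(abs(diff(fwhm) - diff(fwhm)[1])), 1e-12)
})

test_that("simulate_spectrum is seed-deterministic and validates inputs", {
  a <- simulate_spectrum(c(K = 50, Na = 10), n_shots = 3, seed = 11)
  b <- simulate_spectrum(c(K = 50, Na = 10), n_shots = 3, seed = 11)
  for (i in 1:3) expect_identical(a[[i]]$intensity, b[[i]]$intensity)
  c2 <- simulate_spectrum(c(K = 50, Na = 10), n_shots = 1, seed = 12)
  expect_false(identical(a[[1]]$intensity, c2[[1]]$intensity))

  expect_error(simulate_spectrum(c(Xx = 5), seed = 1),
               "Xx", class = "libsquant_no_lines")
})

test_that("empty composition with zero noise gives a flat baseline", {
  inst <- instrument_model(range = c(500, 600), step = 0.1, baseline = 7)
  s <- simulate_spectrum(setNames(numeric(0), character(0)),
                         lines = default_line_models("K"),
                         instrument = inst, noise = no_noise())[[1]]
  expect_true(all(s$intensity == 7))
})

test_that("noiseless K-only spectrum has exactly two maxima in 760-775 nm", {
  s <- simulate_spectrum(c(K = 50), noise = no_noise(), seed = 1)[[1]]
  sel <- s$wavelength >= 760 & s$wavelength <= 775
  y <- s$intensity[sel]
  n_max <- sum(y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                 y[2:(length(y) - 1)] >= y[3:length(y)])
  expect_identical(n_max, 2L)
})

test_that("calibration series follows the nine-level spiked design", {
  series <- cached_default_series(seed = 1)
  expect_equal(nrow(series), 9L)
  expect_equal(range(series$concentration), c(1, 144))
  expect_equal(attr(series, "analyte"), "K")
  expect_equal(attr(series, "standard"), c(Na = 10))
  expect_equal(spectrum_meta(series$spectrum[[1]])$shots_accumulated, 2L)

  expect_error(simulate_calibration_series(levels = c(1, -2), seed = 1),
               class = "libsquant_invalid_concentration")

  single <- simulate_calibration_series(levels = 5, noise = no_noise(),
                                        n_shots = 1, seed = NULL)
  expect_equal(nrow(single), 1L)
  again <- simulate_calibration_series(levels = 5, noise = no_noise(),
                                       n_shots = 1, seed = NULL)
  expect_identical(single$spectrum[[1]]$intensity,
                   again$spectrum[[1]]$intensity)
})

test_that("noiseless analyte doublet area is exactly linear in level", {
  levels <- c(1, 12, 144)
  series <- simulate_calibration_series(levels = levels, standard = c(Na = 0),
                                        noise = no_noise(), n_shots = 1,
                                        seed = NULL)
  # integrate the baseline-subtracted signal over the full grid; the only
  # deviation from exact linearity is sub-percent tail truncation
  grid_area <- vapply(series$spectrum, function(s) {
    pracma::trapz(s$wavelength, s$intensity - 10)
  }, numeric(1))
  # S_K * sum(rel) = 100 * 1.5 per unit concentration
  expect_equal(grid_area / levels, rep(150, 3), tolerance = 0.01)
})
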