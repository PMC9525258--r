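test_that("detect_peaks is prominence-based and offset-invariant", {
  grid <- seq(586, 600, by = 0.05)
  flat <- libs_spectrum(grid, rep(5, length(grid)))
  expect_equal(nrow(detect_peaks(flat)), 0L)

  s <- simulate_spectrum(c(K = 50), noise = no_noise(), seed = 1)[[1]]
  cand <- detect_peaks(s, min_prominence = 10)
  expect_equal(nrow(cand), 2L)
  expect_equal(cand$center, c(766.39, 769.98), tolerance = 0.05 / 766)
  expect_true(all(diff(cand$center) > 0))  # ordered by wavelength

  shifted <- libs_spectrum(s$wavelength, s$intensity + 500)
  expect_equal(detect_peaks(shifted, min_prominence = 10)$center,
               cand$center)
})

test_that("a noiseless single Lorentzian is recovered to high precision", {
  s <- lorentz_spectrum(766.39, 0.5, 100, baseline = 3,
                        window = c(756, 776))
  pk <- fit_multiplet(s, window = c(763, 773), k = 1)
  expect_true(pk$converged)
  expect_equal(pk$center, 766.39, tolerance = 1e-6)
  expect_equal(pk$fwhm, 0.5, tolerance = 1e-6)
  expect_equal(pk$amplitude, 100, tolerance = 1e-6)
  expect_equal(attr(pk, "baseline"), 3, tolerance = 1e-6)
  expect_equal(pk$area, (pi / 2) * 100 * 0.5, tolerance = 1e-6)

  # analytic area vs trapezoid quadrature of the fitted curve over a wide
  # window (+/- 150 w keeps Lorentzian tail truncation near 0.2%)
  xq <- seq(pk$center - 150 * pk$fwhm, pk$center + 150 * pk$fwhm,
            length.out = 20001)
  quad <- pracma::trapz(xq, lorentz(xq, pk$center, pk$fwhm, pk$amplitude))
  expect_equal(pk$area, quad, tolerance = 5e-3)
})

test_that("the K doublet is separated into two components at truth", {
  s <- simulate_spectrum(c(K = 50), noise = no_noise(), seed = 1)[[1]]
  pk <- fit_multiplet(s, window = c(763, 773), k = 2)
  expect_equal(nrow(pk), 2L)
  expect_lt(abs(pk$center[1] - 766.39), 0.01)
  expect_lt(abs(pk$center[2] - 769.98), 0.01)
  # analytic areas equal the simulator's photon budget per line
  expect_equal(pk$area, c(5000, 2500), tolerance = 1e-4)
})

test_that("degenerate and ill-conditioned windows are flagged, not silent", {
  grid <- seq(586, 600, by = 0.05)
  zero <- libs_spectrum(grid, rep(0, length(grid)))
  pk <- fit_multiplet(zero, window = c(588, 594), k = 1)
  expect_equal(pk$amplitude, 0)
  expect_equal(pk$status, "degenerate")
  expect_false(pk$converged)

  one_peak <- lorentz_spectrum(590, 0.5, 100, window = c(586, 600))
  expect_warning(fit_multiplet(one_peak, window = c(588, 594), k = 3),
                 "ill-conditioned")

  expect_error(fit_multiplet(one_peak, window = c(589.9, 590.1), k = 2),
               class = "libsquant_fit_error")
})

test_that("random noiseless peaks are recovered below 1e-4 relative error", {
  set.seed(101)
  n_cases <- 30
  worst <- 0
  for (i in seq_len(n_cases)) {
    A <- 10^runif(1, 0, 4)
    w <- runif(1, 0.1, 2)
    c0 <- runif(1, 605, 615)
    s <- lorentz_spectrum(c0, w, A, baseline = runif(1, 0, 20),
                          window = c(600, 620))
    pk <- fit_multiplet(s, window = c(600, 620), k = 1)
    worst <- max(worst,
                 abs(pk$center - c0) / c0,
                 abs(pk$fwhm - w) / w,
                 abs(pk$amplitude - A) / A)
  }
  expect_lt(worst, 1e-4)
})

test_that("doublet components separate at widths up to 1.5 nm under 1% noise", {
  for (w0 in c(0.5, 1.0, 1.5)) {
    lines <- dplyr::bind_rows(
      line_model("K", 766.39, rel_strength = 1, w0 = w0, beta = 0,
                 sensitivity = 100),
      line_model("K", 769.98, rel_strength = 0.5, w0 = w0, beta = 0,
                 sensitivity = 100))
    s <- simulate_spectrum(c(K = 50), lines = lines,
                           noise = noise_model(0, 0.01, 0, seed = NULL),
                           seed = 300 + round(10 * w0))[[1]]
    pk <- fit_multiplet(s, window = c(763, 773), k = 2)
    expect_lt(abs(pk$center[1] - 766.39), 0.05)
    expect_lt(abs(pk$center[2] - 769.98), 0.05)
  }
})

test_that("refitting from the fitted centers reproduces the fit", {
  s <- simulate_spectrum(c(K = 50), seed = 5)[[1]]
  pk1 <- fit_multiplet(s, window = c(763, 773), k = 2)
  pk2 <- fit_multiplet(s, window = c(763, 773), k = 2, init = pk1$center)
  expect_equal(pk2$center, pk1$center, tolerance = 1e-7)
  expect_equal(pk2$area, pk1$area, tolerance = 1e-6)
})

test_that("peak_area is the analytic Lorentzian integral", {
  expect_equal(peak_area(0, 1), 0)
  expect_equal(peak_area(100, 0.5), 78.5398, tolerance = 1e-6)
  expect_equal(peak_area(100, 1.0), 2 * peak_area(100, 0.5))
  pk <- tibble::tibble(amplitude = c(10, 20), fwhm = c(0.5, 0.25))
  expect_equal(peak_area(pk), (pi / 2) * c(5, 5))
})
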