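# libsquant

Quantitative elemental analysis of laser-induced breakdown spectroscopy
(LIBS) emission spectra, aimed at tissue electrolyte measurements (Na, K,
Ca, and exotic alkaline-earth contaminants such as Ba and Sr).

LIBS reads atomic emission from a laser-produced plasma. At high analyte
abundance, self-absorption (Stark self-broadening) widens each emission
line and suppresses its height, so calibration curves built on **peak
intensity** bend over and acquire large intercepts. The photons are not
lost — they are redistributed in wavelength — so the **integrated peak
area** stays proportional to abundance. `libsquant` implements the
area-based pipeline around this fact:

- **Lorentzian multiplet fitting.** Each emission line is the Lorentzian
  `L(λ) = A (w/2)² / ((λ − λ₀)² + (w/2)²)` with amplitude `A`, FWHM `w`
  and center `λ₀`. `fit_multiplet()` fits `k` components plus a shared
  constant baseline by bounded Levenberg–Marquardt least squares and
  reports each component's analytic area `(π/2) A w` — this is what
  separates the overlapping K resonance doublet at 766.39/769.98 nm into
  two resolved peaks.
- **Element responses and calibration.** `element_response()` sums the
  areas of all matched lines of an element (area mode) or takes the single
  strongest amplitude (intensity mode); `calibrate_series()` normalizes to
  an internal standard (Na) and fits the OLS calibration line
  `response = a + b·c` with its R².
- **Identification.** `match_lines()` assigns fitted peaks to a reference
  line table by greedy nearest-wavelength matching;
  `compare_reference()` scores a spectrum against a pure-salt reference
  spectrum by cosine similarity.
- **Corrected Na/K ratios.** `na_k_ratio()` forms, per laser shot,
  `Σ area(Na) / (1.719 × Σ area(K))` — the 1.719 factor equalizes the
  instrument's Na/K area response for equal molar amounts — and reports
  the mean and shot-to-shot SD.
- **Forward simulator.** `simulate_spectrum()` generates spectra under the
  self-broadening law `w(c) = w₀ (1 + β c)` with area exactly linear in
  concentration, plus baseline, pixel noise and a per-shot lognormal pulse
  factor, all reproducible from one seed — so every stage of the pipeline
  is testable without instrument data.

## Worked example

Nine-level KCl calibration series (1–144 nmol/mm², fixed Na spike, two
accumulated shots per level, default noise), calibrated both ways:

```r
library(libsquant)

series   <- simulate_calibration_series(seed = 1)
cal_area <- calibrate_series(series, mode = "area")
cal_int  <- calibrate_series(series, mode = "intensity")
cal_area
#> <libs_calibration> area mode (normalized): response = -0.00142207 + 0.0727731 * conc, R^2 = 0.999997 (9 points)
cal_int
#> <libs_calibration> intensity mode (normalized): response = 0.298441 + 0.0151468 * conc, R^2 = 0.886211 (9 points)
```

The area-mode curve is linear over the whole range (R² ≈ 1.000) with an
intercept indistinguishable from zero, while the intensity-mode curve of
the *same* spectra loses linearity (R² ≈ 0.886) and picks up a large
intercept-to-slope ratio — the Stark-broadening signature. Predicting a
level back through the area curve:

```r
predict_concentration(cal_area, cal_area$points$response[5])
#> [1] 11.995   # true value 12.000 nmol/mm2
```

Corrected Na/K ratio of a simulated tissue shot series with a true
concentration ratio of 2.18:

```r
shots <- simulate_spectrum(c(Na = 21.8, K = 10), n_shots = 4, seed = 7)
na_k_ratio(shots)
#> <libs_ratio> Na/K = 2.185 +/- 0.008126 over 4 shot(s) (K area corrected by 1.719)
```

`autoplot()` works on spectra (optionally overlaying fitted components)
and calibration curves; `tidy()`/`glance()` return the usual tibbles. A
command-line wrapper is installed at
`system.file("cli", "libsquant", package = "libsquant")` with
`simulate` / `fit` / `identify` / `calibrate` / `quantify` / `ratio`
subcommands (see `?libs_cli`).

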