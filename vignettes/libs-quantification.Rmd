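---
title: "Peak-area quantification of LIBS spectra: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak-area quantification of LIBS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(libsquant)
```

## The measurement problem

Laser-induced breakdown spectroscopy (LIBS) fires a short laser pulse at a
sample, producing a micro-plasma whose atomic emission lines identify and
quantify the elements ablated. For tissue electrolytes the readout of
interest is the abundance of Na, K and Ca — and occasionally rarer
alkaline earths (Ba, Sr) — from a handful of laser shots.

The physical obstacle to naive quantification is self-absorption, often
discussed together with Stark broadening: at high analyte abundance, cold
atoms of the same element re-absorb emitted photons, so the line grows
*wider* while its apparent *height* saturates. A calibration curve built
on peak intensity therefore bends over at high concentration and acquires
a large intercept. Crucially, the photons are redistributed in wavelength
rather than destroyed, so the *integrated* line area remains proportional
to the number of emitting atoms. Everything in this package follows from
that distinction: fit the line shape, compute the area analytically, and
calibrate on areas.

## The line-shape model

Each emission line is modeled as a Lorentzian,

$$L(\lambda) = A\,\frac{(w/2)^2}{(\lambda-\lambda_0)^2 + (w/2)^2},$$

with amplitude $A$ (AU), FWHM $w$ (nm) and center $\lambda_0$ (nm). Its
integral has the closed form $(\pi/2)\,A\,w$, which `peak_area()` uses for
every reported area — quadrature appears only as an independent oracle in
the tests. `fit_multiplet()` fits $k$ Lorentzians plus one shared constant
baseline per window by bounded Levenberg–Marquardt least squares
(`minpack.lm`). A joint multi-component fit is essential for the K
resonance doublet: the 766.39 and 769.98 nm lines are only 3.59 nm apart
and overlap visibly once broadened, but the joint fit returns two fully
resolved components whose areas can be summed.

The constant-per-window baseline is deliberate: on an ash-free filter
substrate a blank shows no metal lines and essentially no structured
background, so the simplest background model consistent with the data is a
constant offset, and no background-spectrum subtraction is performed.

### Numerical choices in the fitter

* **Initialization.** Candidate centers come from a topographic-prominence
  peak detector (prominence is invariant to constant offsets, so no
  baseline estimate is needed); initial amplitudes are the heights above
  the window minimum and the initial FWHM is four grid steps. When
  reference wavelengths are known (calibration, ratio pipelines) they are
  passed as `init` instead.
* **Bounds.** $A \ge 0$, $\lambda_0$ inside the window, $w$ between a
  quarter grid step and twice the window width.
* **Convergence.** Relative tolerance $10^{-10}$ on cost and parameters,
  up to 500 iterations, then up to three restarts from deterministically
  jittered starting points (a fixed jitter pattern keeps the fit path free
  of random numbers). Non-convergence is returned as a flagged status,
  never silently; an all-flat window short-circuits to an explicit
  `"degenerate"` result with zero amplitude; asking for more components
  than there are detectable candidates triggers an ill-conditioning
  warning.
* **Tie-breaks.** When more candidates than components exist, the $k$ most
  prominent are kept; fitted components are returned sorted by center.

## The forward simulator

The paperless validation strategy rests on a generator whose physics is
the package's own formalization of the qualitative self-broadening
picture; no closed-form law is standard, so one was chosen that reproduces
every qualitative behavior of interest:

* FWHM linear in concentration: $w(c) = w_0\,(1 + \beta c)$;
* photon conservation: line area exactly $S \cdot c \cdot r$ for
  sensitivity $S$ and relative line strength $r$, hence amplitude
  $2 S c r / (\pi w)$ — increasing but concave in $c$.

With $\beta > 0$ this yields, by construction: broader and flatter peaks
at high concentration when low- and high-concentration spectra are
overlaid; a curved intensity calibration with inflated intercept; and a
linear area calibration — the orderings the pipeline is designed to
exploit and which the acceptance tests check.

Defaults (all overridable per line): grid step 0.05 nm (≥ 6 points per
0.3 nm FWHM), $w_0 = 0.30$ nm, $\beta = 0.02$ per nmol/mm², so the width
roughly quadruples across the 1–144 nmol/mm² calibration range. Noise
defaults: additive detector noise 0.5 AU, per-pixel multiplicative noise
1 %, per-shot lognormal pulse factor with 5 % fractional sd (unit mean),
baseline 10 AU, all drawn from a single integer seed; zero-noise
simulation touches no RNG. The instrument range defaults to the
127–868 nm span of a broadband LIBS spectrometer.

The calibration generator emulates a nine-level KCl dilution series
spanning 1–144 nmol/mm² — log-spaced, since the stated design fixes only
the endpoints and count, and log spacing probes the low end where
intensity calibrations fail — each level spiked with a fixed 10 nmol/mm²
Na internal standard and accumulated over two laser shots, matching a
two-shots-per-data-point acquisition scheme.

**What the simulator does not emulate.** Pure Lorentzian shapes only: the
central self-absorption "dip" that extreme optical depth carves into a
line is deliberately not modeled, nor are molecular bands (CN, CaO, CaOH),
continuum plasma emission decay, depth-dependent sample depletion across
shots, Saha–LTE level populations, or matrix effects of wet, inhomogeneous
tissue. Passing tests therefore demonstrate the *analysis chain* is
correct under the stated line-shape physics; they do not certify accuracy
on real tissue spectra, where shape distortions and unmodeled emitters
add bias the simulator cannot reveal.

## Sensitivities and the Na/K correction factor

`na_k_ratio()` computes, per shot,
$\mathrm{ratio} = \sum \mathrm{area(Na)} / (f \cdot \sum \mathrm{area(K)})$
over the Na 589.18/819.22 nm and K 766.39/769.98 nm lines, with
$f = 1.719$ by default. The factor is an empirical instrument-response
equalizer: multiplying the summed K area by it makes equal molar amounts
of Na and K produce equal corrected areas. It has no first-principles
derivation here, so it is exposed as an explicit argument and documented
as valid only for this line set; the function never adapts it silently.

The simulator's default per-element sensitivities encode the same
asymmetry ($S_{\mathrm{Na}} \Sigma r_{\mathrm{Na}} = 1.719 \times
S_{\mathrm{K}} \Sigma r_{\mathrm{K}}$), so the default correction recovers
a true concentration ratio on simulated tissue — which is exactly the
property the ratio tests verify. Relative line strengths within an
element (K 766:770 = 1:0.5, Na 589:819 = 1:0.25) are nominal fixture
values, as are the Ca/Ba/Sr entries of the packaged table; only the Na
and K wavelengths are authoritative.

Reporting is mean-of-ratios with its SD over the first four single-shot
spectra (a per-shot dispersion is wanted), not ratio-of-means. Because
both elements share each shot's plasma, the lognormal pulse factor cancels
exactly in the ratio; with shot-factor noise only, the per-shot ratios are
constant to fit precision.

## Calibration conventions

* Area mode sums the areas of *all* matched lines of the element — every
  detected photon represents an emitting atom, so all transition pathways
  count. Intensity mode takes the single strongest matched amplitude, the
  conventional readout it is contrasted with.
* Normalization divides by the internal standard's response in the same
  mode, using only the Na D region (586–592 nm window); the calibration's
  R² is computed on normalized responses. Without pulse-energy variation,
  normalized and unnormalized calibrations agree in R² to $10^{-3}$,
  which the tests use as a neutrality check.
* The calibration line is unweighted OLS (`stats::lm`); heteroscedastic
  weighting is out of scope.

## Identification conventions

`match_lines()` uses greedy nearest-$\Delta\lambda$ assignment with a
0.15 nm default tolerance (half the default base FWHM): all peak–line
pairs within tolerance are ranked by distance (ties to the stronger line)
and accepted subject to one-peak-per-line and one-line-per-peak, which
also settles conflicts between elements in favor of the closer line. An
element's score is its matched relative strength over the total strength
of its in-range table lines. `compare_reference()` scores a sample
against a pure-salt reference spectrum by cosine similarity of
median-subtracted intensities on the common grid (the median stands in
for the flat baseline; a flat spectrum scores 0 by convention).

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen to
exercise every code path with comfortable statistical margins: the full
nine-level series at two shots per level on the full 127–868 nm grid
(~14 800 points per spectrum), 100 randomized single-peak recovery
instances, 50-shot normalization experiments and 4-shot ratio analyses.
The whole suite completes in well under a minute on one core.

## Known limitations

* The Stark law ($w$ linear in $c$, area exactly linear) is a
  single-parameter idealization; real broadening is density- and
  temperature-dependent and line-specific.
* Voigt/Gaussian instrumental convolution is not modeled or fitted; on
  real spectrometers with Gaussian instrument functions, Lorentzian-only
  fits bias FWHM slightly.
* Windows with more than ~5 components are refused rather than fitted.
* The correction factor 1.719 and all relative strengths are tied to the
  default line set; changing the table requires re-deriving both.
* Concentration prediction inverts the calibration line without
  propagating calibration uncertainty into the prediction.
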