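Package: libsquant
Title: Quantitative Analysis of Laser-Induced Breakdown Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative elemental analysis of laser-induced breakdown
    spectroscopy (LIBS) emission spectra. Provides Lorentzian multiplet
    fitting with analytic peak areas, prominence-based peak detection,
    reference-line element identification, internal-standard calibration
    curves in peak-area and peak-intensity modes, and corrected Na/K
    elemental ratio estimation, together with a seeded forward simulator
    of Stark self-broadened emission spectra so every stage of the
    pipeline can be validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
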