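Package: specklegram
Title: Simulation, Demodulation and CNN Quantification of Fiber Specklegram
    Biosensor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multimode-fiber specklegram biosensor data
    for label-free quantification of the tumor biomarker CEACAM5. Provides a
    seed-reproducible forward simulator of multimode interference specklegrams
    with a concentration-dependent dose-response perturbation of guided-mode
    phases and powers, the standard image preprocessing chain (grayscale,
    unit-range normalization, block-mean downsampling), zero-mean normalized
    cross-correlation (ZNCC) demodulation, four-parameter logistic and linear
    dose-response calibration with closed-form inversion, and a compact
    two-dimensional convolutional neural network that decodes specklegrams to
    concentration via probability-weighted averaging over a concentration
    panel. A pipeline orchestrator reproduces the full analysis (simulate,
    preprocess, correlate, calibrate, train, evaluate) from a single
    configuration and seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    minpack.lm,
    yaml,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
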