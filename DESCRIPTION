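Package: spectrograin
Title: Hyperspectral Reflectance Pipeline for Seed Variety Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Chemometric pipeline for identifying crop seed varieties from
    hyperspectral reflectance spectra. Provides panel-based reflectance
    calibration and region-of-interest extraction from ENVI hypercubes, six
    spectral pretreatments (Savitzky-Golay smoothing, first derivative,
    standard normal variate, multiplicative scatter correction, FFT low-pass
    filtering, Hilbert transform), three wavelength/feature extraction
    methods (competitive adaptive reweighted sampling, the successive
    projections algorithm, and Kaiser-rule principal components) backed by a
    NIPALS partial-least-squares engine, five classifiers behind one
    fit/predict contract, and a factorial benchmark that evaluates every
    pretreatment x selector x classifier combination under a stratified
    split with leakage-safe cross-validation. A seeded synthetic-spectra
    generator reproduces the statistical structure of seed reflectance data
    so the whole pipeline is testable without proprietary images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    signal,
    class,
    withr,
    optparse
Config/testthat/edition: 3
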