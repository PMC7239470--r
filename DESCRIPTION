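Package: chromaplast
Title: Quantifying Plastic Structural Coloration from Reflectance Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying temperature-dependent (plastic) structural
    coloration from reflectance spectra. Provides spectral processing
    (interpolation to a 1 nm grid, loess smoothing, replicate handling),
    hue, brightness and a family of spectral saturation metrics over fixed
    and peak-tracking wavelength bands (including a capped peak-tracking
    metric robust to long-wavelength background reflectance), a tetrapod
    visual-sensitivity model (A1 visual-pigment templates, quantum catches,
    tetrahedral colour space, hue-corrected saturation r.achieved), and the
    mixed-model statistical framework used to compare metrics: repeatability,
    a random-slope reaction-norm model ladder with likelihood-ratio tests,
    slope-intercept correlations, and cross-environment Spearman rank
    preservation. A calibrated synthetic-spectra generator emulating a
    green-to-blue thermally shifting ornament over a long-wavelength
    background supports simulation studies and testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
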