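Package: palseg
Title: HIFU Lesion Segmentation in Multi-Wavelength Photoacoustic Images
Version: 0.1.0
Authors@R:
    person("palseg", "developers", email = "palseg@example.org", role = c("aut", "cre"))
Description: Tools to detect high-intensity focused ultrasound (HIFU) thermal
    lesions in multi-wavelength photoacoustic (MWPA) image cubes. Implements
    the physics-based two-step spectral normalization (laser-fluence and
    per-pixel maximum normalization), a synthetic MWPA phantom driven by the
    photoacoustic forward model, pixel-level dataset assembly with class
    balancing, four per-pixel classifiers (quadratic discriminant analysis,
    a single-hidden-layer neural network, a radial-basis-function support
    vector machine, and a random forest), a six-layer fully convolutional
    segmentation network trained with class-weighted cross-entropy, greedy
    sequential forward wavelength selection, data augmentation, and an
    evaluation harness producing recall/precision/F1 grids across reduced
    wavelength sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    rhdf5,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
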