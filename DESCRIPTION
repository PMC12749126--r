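Package: brainmech
Title: Two-Scale Brain Biomechanics: MRE Elastogram Reconstruction and AFM
    Nanoindentation Analysis
Version: 0.1.0
Authors@R:
    person("Brainmech", "Developers", email = "brainmech@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for measuring brain mechanical properties at
    two scales. The tissue-level stage simulates and reconstructs magnetic
    resonance elastography (MRE) acquisitions: harmonic shear-wave
    displacement fields are encoded into wrapped motion-encoding-gradient
    phase images, recovered by polarity differencing, slice-wise quality-guided
    phase unwrapping and temporal harmonic extraction, and inverted to
    storage/loss modulus and shear stiffness maps by algebraic Helmholtz
    inversion with per-region-of-interest statistics. The cell-level stage
    simulates and analyses atomic force microscopy (AFM) nanoindentation:
    spherical-indenter force curves are reduced to per-cell Young's moduli by
    contact-point detection and a linearized Hertz-model fit, with Welch group
    comparison. A synthetic-data module provides ground-truth phantoms and
    force curves so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
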