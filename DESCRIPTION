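Package: braincalib
Title: Heterogeneous Brain Material Calibration from MRE Stiffness Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calibrating heterogeneous quasi-linear viscoelastic
    (Ogden-QLV) brain material models against measured displacement signals.
    Implements magnetic resonance elastography (MRE) stiffness-map truncation,
    median normalization and relative-stiffness binning; the one-term Ogden
    hyperelastic law with a Prony-series reduced relaxation function, including
    frequency-domain response and tan(delta) fitting; CORA-style objective
    rating of three-axis displacement time histories with composite (cCORA)
    and receiver-weighted (wcCORA) scores; a two-stage golden-section inverse
    calibration of the median infinitesimal shear modulus and the Ogden
    non-linearity coefficient; maximum-principal-strain metrics (MPS-95,
    threshold-exceedance volume fractions, regional summaries); and a
    desk-scale spring-network phantom that generates synthetic experiment
    bundles for end-to-end testing of the calibration machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
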