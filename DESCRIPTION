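Package: synergykit
Title: Temporal and Spatial Muscle Synergy Analysis for Assisted
    Sit-to-Stand and Stand-to-Sit Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to extract and compare temporal and spatial muscle
    synergies from multi-channel surface EMG recorded during sit-to-stand
    and stand-to-sit movements performed with different levels of rollator
    support. Implements the complete analysis chain: a synthetic-data
    generator with known ground-truth synergies and planted support
    effects, EMG preprocessing (band-pass/notch filtering, ECG-artifact
    template subtraction, envelope computation, kinetic event detection,
    time normalization, amplitude normalization), non-negative matrix
    factorization with cross-validated model-order selection (R-squared
    knee and global/local criteria), constrained k-means++ matching of
    activation profiles across movement strategies, full-width at
    half-maximum timing analysis, and multivariate linear mixed models
    on synergy muscle weightings across support conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    pracma,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
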