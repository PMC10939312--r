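Package: esfm
Title: Forward Models of Expectation Suppression in Visual Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates feature-tuned neural populations and their modulation by
    perceptual expectations (dampening, sharpening, tuning and global variants),
    maps population activity to noisy fMRI-like voxel data by biased sampling,
    computes seven voxel-level outcome metrics (amplitude suppression,
    correlation-based pattern metrics and rank-profile metrics), and identifies
    the neural modulation that best accounts for an empirical or synthetic
    result by sign matching and weighted mean-squared-error grid search under
    biological plausibility constraints. Includes representational similarity
    tools for validating one-dimensional stimulus feature spaces (orientation
    energy, shape complexity, semantic similarity) and a synthetic-data
    generator emulating probabilistic image-transition designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    parallel,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    vegan,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
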