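Package: tosccamm
Title: Sparse Canonical Correlation Analysis for Repeated Measurements
    with Latent Trajectories
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Thresholded ordered sparse canonical correlation analysis for
    two high-dimensional longitudinal datasets with irregularly and sparsely
    observed visits (TOSCCA-MM). Canonical weights are held fixed across
    measurements while the time dynamics are modelled on the low-dimensional
    latent variables through pluggable longitudinal trajectory models
    (random-intercept linear, polynomial and change-point mixed models)
    inside a NIPALS loop with exact-cardinality soft-thresholding.
    Includes cross-validation over sparsity grids, adjusted cumulative
    percentage of explained variance, permutation testing for the number of
    components, and a synthetic-data generator for longitudinal two-view
    data with a shared dynamic latent variable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
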