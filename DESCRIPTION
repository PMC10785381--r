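Package: nnagp
Title: Genomic Prediction with Nearest-Neighbour Spatial Adjustment for
    Semi-Field Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic prediction of above-ground and root traits in
    semi-field row experiments grown under a water-availability gradient.
    Implements two nearest-neighbour spatial covariance structures built from
    row-neighbourhood loading matrices (an indicator-window structure and a
    Euclidean-distance-weighted structure), a dense AI-REML engine with EM
    fallback for multi-kernel linear mixed models, the VanRaden genomic
    relationship matrix with SNP quality control, derivation and editing of
    grain and minirhizotron root-image traits, genetic-parameter estimation
    (phenotypic variance, narrow- and broad-sense heritability, genetic
    coefficient of variation), leave-one-line-out cross-validation with
    predictive ability, prediction accuracy, dispersion diagnostics, bootstrap
    standard errors and the Hotelling-Williams test, and a synthetic-data
    generator that emulates the full experimental design for testing and
    simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
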