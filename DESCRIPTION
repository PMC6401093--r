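Package: gustotope
Title: Searchlight Decoding and Representational Analysis of Gustatory
    fMRI Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping taste-quality representations in human
    gustatory cortex from event-related fMRI: trial-wise GLM pattern
    extraction, split-half univariate tuning analyses, searchlight linear
    discriminant decoding with leave-one-stimulus-pair-out
    cross-validation, sign-flip maximum-statistic permutation inference
    with familywise error control, taste conjunction and
    leave-one-subject-out ROI analyses, and representational similarity
    analyses separating taste type from hedonic valence.  Includes a
    seeded synthetic BOLD generator with planted taste-selective and
    valence-selective spatial patterns so that every stage of the
    pipeline can be validated against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    car,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
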