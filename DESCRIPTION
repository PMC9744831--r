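Package: ladrive
Title: Leukoaraiosis Volumetry and Driving-Safety Path Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Threshold-based white-matter-hyperintensity (leukoaraiosis)
    volumetry on FLAIR-like volumes with middle-cerebellar-peduncle
    referenced intensity standardization, polynomial bias-field correction
    and lobar/periventricular parcellation; brain-atrophy and behavioral
    (dynamic visual cognition, driving safety performance) scoring; and a
    covariance-based path-analysis and standardized-regression stage with
    GFI/AGFI/RMSEA fit indices. A synthetic-data module supplies digital
    phantoms with known lesion ground truth and cohort tables with a
    prescribed correlation structure, so the full pipeline is testable
    without any external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    Matrix,
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
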