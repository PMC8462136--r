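Package: milfoilSDM
Title: Data-Quality Comparison of Occurrence and Abundance Species
    Distribution Models for Invasive Watermilfoil
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and evaluates random-forest species distribution models
    (SDMs) for invasive Eurasian watermilfoil from presence-absence,
    presence-only (random, distant and proximal pseudoabsence draws from
    unsurveyed lakes) and abundance (point-intercept frequency of occurrence)
    response data. Includes an inverse-distance spatial autocovariate,
    permutation Moran's I residual diagnostics, pair-correlation-function
    block sizing, spatially blocked cross-validation, discrimination accuracy
    (AUC, TSS, Kappa under nonindependent, quasi-independent and spatially
    blocked evaluation) and functional accuracy (abundance-suitability
    correlations and quantile-regression wedge strength), together with a
    seeded virtual lake landscape generator so the full pipeline can be
    exercised and tested without the original survey data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    randomForest,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
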