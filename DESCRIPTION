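Package: deupanel
Title: Duplicate-Measured Expression Panel Analysis Across Deuterium Concentrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for small expression panels measured in
    technical duplicate across graded deuterium concentrations (40, 80,
    150 and 300 ppm, with 150 ppm as the physiological control). Provides
    quality-control filtering driven by the duplicate coefficient of
    variation and propagated ratio errors, symbolic discretization of
    three-point expression trajectories, a three-way outlier consensus
    (global-centroid distance, DBSCAN density outliers and singleton
    symbolic patterns), and tied-covariance Gaussian-mixture module
    discovery with BIC/silhouette model selection, leave-one-out
    stability, Mahalanobis boundary diagnostics and cluster-transition
    tables. A synthetic-panel generator with known ground truth makes
    every stage testable without access to the original measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    cluster,
    jsonlite,
    mclust,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
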