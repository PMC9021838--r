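Package: trajshift
Title: Detect Temporal Expression Pattern Shifts Between Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters per-replicate time-course gene-expression trajectories
    from two experimental conditions with soft dynamic-time-warping K-means
    followed by Dirichlet-process Gaussian-process refinement, sorts
    biological replicates by cluster consistency without averaging them, and
    reports genes whose temporal expression pattern shifts between the two
    conditions (off-to-dynamic, dynamic-to-off, dynamic-to-dynamic), with
    Fisher's exact functional enrichment of the resulting trajectory sets.
    Includes a synthetic expression-matrix generator with known trajectory
    shapes and injected shifts for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    limma,
    data.table,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
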