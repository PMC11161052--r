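Package: puttyclust
Title: Silhouette-Guided Cluster Refinement and Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the SillyPutty heuristic, which refines a cluster
    assignment by repeatedly moving the sample with the most negative
    silhouette width to its nearest foreign cluster until every silhouette
    is non-negative. Provides random-restart and warm-start drivers,
    per-sample silhouette profiles, external and internal cluster validity
    indices (adjusted Rand index, normalized entropy, within-group sum of
    squares, perfect classification counts), a block-signature simulator of
    cluster-structured log-expression data with additive Gaussian noise,
    and a benchmark harness comparing the heuristic and its hybrids against
    standard clustering algorithms on a grid of simulated data sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    kernlab
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
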