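Package: scnmod
Title: Modular Organization Analysis of Structural Covariance Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds group-level structural covariance networks from tables of
    regional cortical thickness, finds their modular organization by weighted
    Newman modularity with a seeded multi-restart Louvain optimizer, and
    derives module-level (intra- and inter-module connectivity) and node-level
    (intra-module degree, participation coefficient) metrics. Group
    differences are assessed with an edge-weight permutation null for
    modularity, subject-relabeling permutation tests for any network measure,
    and edge-wise Fisher r-to-z comparisons with Benjamini-Hochberg false
    discovery rate control. A planted-partition synthetic cohort generator
    with covariate effects supports validation and power exploration without
    access to restricted imaging data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
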