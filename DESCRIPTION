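Package: diffcornet
Title: Differential Co-Expression Network Analysis for Sparse Single-Cell
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers gene pairs whose co-expression changes between two groups
    of single cells from sparse scRNA-seq matrices. Pearson correlations are
    computed per cellular state over the cells in which both genes are
    detected (dropout masking), converted to sample-size-adjusted interaction
    scores by the Fisher z-transformation, and the change in absolute
    interaction strength between states is tested with the exact closed-form
    null distribution of the difference of absolute standard normal variables,
    so no permutation testing is needed. Includes network assembly with hub
    ranking, Cytoscape-compatible exports, a synthetic-data generator, and a
    simulation engine for power and error-rate studies under tunable
    covariance, noise power, cell number and dropout fraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
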