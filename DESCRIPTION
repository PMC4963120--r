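Package: dynbic
Title: Genetic-Algorithm Biclustering of Time-Series Expression Data for
    Dynamic Protein Complex Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Mines co-regulated gene/time-point biclusters from time-series
    gene expression data with a binary-encoded genetic algorithm driven by a
    discretized column-based fitness measure, extracts one induced "dynamic"
    protein-protein interaction subnetwork per bicluster, runs a pluggable
    protein-complex detector on each subnetwork, aggregates the predictions,
    and scores them against gold-standard complex sets with Jaccard-based
    precision, recall and F1. Includes four expression discretization
    techniques, a synthetic-data generator with planted biclusters and
    planted complexes for ground-truth validation, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
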