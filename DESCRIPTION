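Package: subspacer
Title: Projected Clustering and Subspace-Cluster Analysis for
    High-Dimensional Labeled Tabular Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for finding and comparing axis-parallel subspace clusters
    in high-dimensional record-by-dimension tables such as clinical cohorts.
    Implements the PROCLUS projected-clustering algorithm with parameter
    sweeps that pool clusters across runs, set-based dissimilarities between
    subspace clusters (Jaccard, Dice, overlap coefficient) on either the
    member or the dimension sets, entropy and purity scoring against class
    labels, multidimensional-scaling overviews, heatmap seriation,
    aggregation tables and table-lens exports, and a class-split /
    dominant-dimension-refinement workflow.  A seeded generator plants
    subspace clusters, globally dominant dimensions, class labels and
    missing values in synthetic data for benchmarking and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    foreign,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
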