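Package: ghostmap
Title: Quantification, Spatial Statistics and Patch-Seq Analysis of
    Lineage-Traced 'Ghost' Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for lineage-traced neuronal populations in
    which a subset of reporter-positive cells no longer expresses the identity
    marker ('Ghost' cells). Provides per-cell fluorescence quantification from
    multichannel image stacks (thresholded connected-component segmentation in
    2D projections or 3D), marker-based cell classification and cohort
    statistics; 3D kernel density estimation of cell point clouds with
    node-wise subpopulation testing and Gaussian cumulative-distribution
    comparison by an extra-sum-of-squares F-test; whole-cell patch-clamp
    feature extraction (input resistance, resting potential, rheobase, action
    potential shape) and rule-based hormone-response classification; and
    patch-seq count-matrix clustering (Leiden with silhouette-based resolution
    selection), relative-expression summaries and diet-driven
    cluster-composition tests. A synthetic-data module generates image stacks,
    point clouds, electrophysiology cohorts and negative-binomial count
    matrices with known ground truth so that every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
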