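Package: microglia3d
Title: Automated 3D Microglial Morphometry, State Clustering and Group Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for phenotyping microglia from 3D
    fluorescence image stacks. Cells are segmented by thresholding and
    26-connected component labelling, and eight morphometric features are
    extracted per cell (convex-hull territorial volume, voxel cell volume,
    ramification index, skeleton endpoint and branchpoint counts, and
    geodesic endpoint-to-centroid branch lengths). Feature tables are
    z-scored, redundancy-filtered by pairwise correlation, clustered with
    partitioning around medoids (PAM) after gap-statistic model selection,
    embedded with UMAP for visualization, and mapped to surveillant, primed
    and activated microglial states. Per-animal state proportions feed an
    effect-size oriented statistical battery (independent t-tests, two-way
    sex-by-state ANOVA, Cohen's d). A synthetic-data module generates
    3D microglia-like image stacks and calibrated per-cell feature tables
    with ground-truth labels so the whole pipeline is testable without
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    car,
    jsonlite,
    nortest,
    stats,
    tiff,
    utils,
    uwot,
    yaml
LinkingTo: Rcpp
Suggests:
    caret,
    cluster,
    igraph,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
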