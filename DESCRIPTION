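Package: dynfc
Title: Dynamic Functional Brain-Network Analysis for Multi-Condition Rodent fMRI
Version: 0.1.0
Authors@R:
    person("dynfc", "maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for resting-state BOLD network analysis across
    awake and anesthetized conditions: signal cleaning (motion censoring,
    nuisance regression, band-pass filtering, mask-normalized spatial
    smoothing), static region-level functional connectivity with edge-wise
    group statistics and matrix-similarity analysis, sliding-window dynamic
    connectivity with k-means brain-state clustering and Davies-Bouldin model
    selection, time-resolved nodal graph metrics on sparsity-thresholded
    binary networks, and voxel-level intrinsic-activity indices with Kendall's
    W concordance and dynamic-architecture stability maps. Ships a
    regime-switching multivariate BOLD simulator so every stage is testable
    without acquired data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
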