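Package: ripplemap
Title: Topological Analysis of Sharp-Wave Ripple Waveforms
Version: 0.1.0
Authors@R:
    person("Ripplemap", "Developers", email = "ripplemap@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for hippocampal sharp-wave ripples (SWRs)
    recorded from laminar local field potentials. Detects and peak-centers
    ripple events on the pyramidal-layer channel, extracts spectral and
    temporal features and current source density (CSD) summaries, projects
    events into a high-dimensional waveform space, and characterizes that
    space with persistent homology (Vietoris-Rips barcodes, Betti numbers),
    angle-based intrinsic dimension estimation, and the Structure Index, a
    k-nearest-neighbor bin-overlap statistic. Embedding geometry tools cover
    UMAP/Isomap/PCA reduction, voxel-based spatial correlation, density
    contour categorization, centroid statistics with bootstrap and shuffle
    controls, rigid embedding alignment, and decoding of layer-resolved CSD
    from waveform-space coordinates. A synthetic-data module generates
    ripples, geometric ground-truth objects, and laminar sessions with known
    couplings so every stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    MASS,
    RANN,
    uwot,
    vegan,
    e1071,
    minpack.lm,
    xgboost,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
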