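Package: cryocontrast
Title: Dual-Agent Contrast Analysis for 3D Fluorescence Cryo-Imaging Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative comparison of the spatial distributions of two
    fluorescence-guided-surgery agents (an ALA-PpIX-like rim-enhancing
    channel and a second-window-ICG-like core-enhancing channel) in
    co-registered whole-brain 3D volumes. Provides volume and mask I/O
    (NRRD, NIfTI-1, numbered TIFF stacks), Euclidean-distance-transform
    based concentric shell decomposition of a tumor mask, tumor-to-
    background and contrast-to-noise ratios for whole-tumor and 1 mm
    margin definitions, distance-resolved shell intensity profiles, line
    profiles, 100-bin bivariate joint histograms, region-restricted
    Pearson cross-correlation, a seeded synthetic dual-agent brain
    phantom generator with analytic ground truth, and a config-driven
    analysis pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    tiff,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
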