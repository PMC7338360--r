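Package: roawake
Title: Astrocytic Calcium Event Detection and Sleep-Wake State Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects spatiotemporal astrocytic calcium events (regions of
    activity, ROAs) in two-photon fluorescence movies by noise-calibrated
    delta-F-over-F thresholding and 3D connected-component labeling, and
    relates them to behavioral state. Includes rule-based sleep-wake scoring
    from ECoG/EMG/motion traces, microarousal and sleep-spindle detection,
    state-specificity analysis of activation maps via Jaccard distances and
    PERMANOVA, transition-locked onset statistics with a causal smoothing
    kernel, conventional ROI trace analysis with neuropil correction, and a
    ground-truthed synthetic data generator so every stage is testable
    without experimental recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    signal,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
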