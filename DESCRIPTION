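Package: widecal
Title: Wide-Field Calcium Imaging Processing and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end processing and analysis pipeline for wide-field
    single-photon calcium imaging movies of densely labelled neural tissue.
    Provides homomorphic contrast enhancement and phase-correlation rigid
    motion correction, activity-based detection of single-frame regions of
    interest with an adaptive z-score threshold, clustering of single-frame
    detections into per-neuron multi-frame ROIs, fluorescence trace
    extraction with dF/F normalization, signal-to-noise and photobleaching
    estimates, trial-aligned task-modulation statistics for trace
    conditioning experiments, and spatial statistics on ROI centroids
    (median-distance resampling test, fixed-radius adjacency counts,
    rank-sum comparison). A synthetic-movie simulator with full ground
    truth (planted somata, transient times, rigid motion, illumination
    non-uniformity, bleaching, trial schedule and modulation labels) makes
    every stage testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml,
    Matrix,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
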