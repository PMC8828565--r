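Package: beamadapt
Title: Adaptive Spatial Filtering for EEG Cognitive-Workload Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-class cognitive-workload decoding from multichannel
    EEG under condition-to-condition non-stationarity. Implements common
    spatial patterns (CSP) and a whole-brain-ROI beamformer built on an
    analytic three-shell spherical head model, with unsupervised exponential
    covariance adaptation of the spatial filters, band-power log-variance
    features, shrinkage LDA classification, chronological leave-one-block-out
    cross-validation, cross-condition transfer evaluation with class-wise
    normalized loss, and a synthetic-session simulator that reproduces the
    within-condition versus cross-condition transfer phenomenon.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite
Suggests: testthat (>= 3.0.0), MASS, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
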