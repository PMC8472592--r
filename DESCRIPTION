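Package: thermoflow
Title: Respiratory Flow Pixel Detection in Thermal Video
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects the pixels carrying respiratory flow (the thermal
    signature of exhaled air) in low-resolution thermal video of infants,
    separating them from respiratory-motion pixels that oscillate at thermal
    edges. Five per-window feature maps (gradient, pseudo-periodicity,
    respiration-rate clusters, a correlation map and a signed covariance map)
    are combined into a flow map, and a bank of Gabor filters selects a
    flow-core-pixel whose covariance tracks the flow region over time. The
    package also provides a respiration-rate estimator, an obstructive-apnea
    simulator, a cessation-of-breathing detector with time-based accuracy,
    sensitivity and specificity scoring, pixel-level detection metrics, and a
    synthetic thermal-phantom generator so the whole pipeline is testable
    without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'io.R'
    'preprocess.R'
    'features.R'
    'gabor.R'
    'detector.R'
    'rr.R'
    'apnea.R'
    'evaluation.R'
    'phantom.R'
    'run.R'
    'thermoflow-package.R'
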