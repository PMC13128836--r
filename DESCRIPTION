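Package: pfcapore
Title: Probe-Directed Nanopore Single-Molecule Sensing of Perfluoroalkyl
    Carboxylic Acids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for probe-directed nanopore
    single-molecule sensing of per- and polyfluoroalkyl carboxylic acids
    (PFCAs). Simulates ionic current traces with Poisson capture statistics,
    detects resistive-pulse events, extracts a frequency-modulated
    43-dimension feature vector per event (low-pass and wavelet conditioned
    all-points-histogram statistics), classifies analytes with bagged
    decision trees including greedy forward feature selection and
    interference experiments, fits the linear molecular-volume to
    current-blockade relationship for standard-free signal prediction, and
    performs digital quantification of multiplexed mixtures from event
    interval times with Poisson calibration and limit-of-detection
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
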