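Package: dyadsync
Title: Movement Synchrony, Gaze and Impression Formation in Observed Dyadic Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: End-to-end pipeline linking interpersonal movement synchrony in
    dyadic interaction videos to observers' impression ratings and gaze
    behaviour, exercised on synthetic data with known ground truth. Provides
    motion-energy extraction from grayscale frame sequences, windowed-lagged
    cross-correlation synchrony, balanced high/low-synchrony stimulus segment
    selection, adaptive velocity-threshold detection of fixations, saccades
    and glissades, dynamic area-of-interest dwell-time analysis, and Bayesian
    hierarchical mixed models (Gaussian and Poisson) with directed and
    undirected hypothesis tests and a default-prior Bayes-factor t-test.
    Includes generators for every input the pipeline consumes: coupled
    motion-energy series, pixel-flip video frames, gaze scanpaths with known
    events, dynamic AOI keypoint tracks, and rating and dwell tables from a
    mixed 2x2x2 design with participant and dyad random effects.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    rjags,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
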