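Package: critstate
Title: Neuronal Avalanche and Low-Correlation Resting-State Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis stack for cortico-striatal resting-state dynamics:
    detection of negative/positive local field potential deflections and
    multi-unit activity from multichannel extracellular recordings,
    spatiotemporal avalanche clustering with finite-support discrete
    power-law maximum-likelihood inference and log-likelihood-ratio model
    comparison, shuffle-corrected cross-correlation statistics, a calcium
    imaging dF/F pipeline with summated-increment transient detection,
    functional-connectivity stability R-squared across time segments, and
    involuntary-movement extraction from frame streams. A branching-process
    and calcium-population synthetic-data module provides ground-truth
    inputs so every stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'avalanche.R'
    'calcium.R'
    'correlation.R'
    'critstate-package.R'
    'io.R'
    'movement.R'
    'pipeline.R'
    'powerlaw.R'
    'signal_events.R'
    'synthetic.R'
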