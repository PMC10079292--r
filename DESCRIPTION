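Package: photopeth
Title: Fiber Photometry Denoising and Peri-Event Analysis of Operant Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Processing chain for dual-wavelength (473/405 nm multiplexed)
    fiber photometry recordings with a control-fluorophore reference fiber:
    background subtraction, sequential regression against the control
    fluorophore and the isosbestic channel, and session-level z-scoring.
    Companion tools align the processed signal to behavioral events
    (peri-event matrices, three-sample window means, trapezoidal AUC,
    Pearson correlations with Fisher confidence intervals), parse
    fixed-ratio operant event logs into trials with outcome and latency
    measures, segment lick trains into bouts, detect movement epochs and
    target approaches from open-field trajectories, extract intrinsic
    electrophysiological features from current-clamp sweeps, and quantify
    tract-tracing cell-count ratios. A seeded synthetic-data generator
    produces every input type with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
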