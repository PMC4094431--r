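Package: erdbci
Title: Auto-Calibrating Co-Adaptive ERD-Based Brain-Computer Interface
    Simulation and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Online brain-computer interface (BCI) training based on
    event-related desynchronization (ERD) of sensorimotor rhythms.
    Implements causal log band-power feature extraction from bipolar EEG
    derivations, two-stage trial artifact screening plus autoregressive
    residual-based real-time artifact detection, an auto-calibrating
    linear discriminant classifier with Fisher-criterion feature
    selection and leave-one-out cross-validated training-window
    selection, cue-guided co-adaptive and self-paced (dwell-time
    brain-switch) paradigm state machines, evaluation statistics
    (sample-wise peak accuracy, Youden index over a threshold by
    dwell-time grid, adjusted-Wald chance-level thresholds,
    imbalance-corrected balanced accuracy), and a seeded synthetic EEG
    user model for closed-loop simulation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
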