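Package: epee
Title: Entropy- and Patience-Based Early Exiting for Multi-Exit Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Adaptive-depth inference for multi-exit transformer classifiers.
    Attaches an affine exit head to every layer of a small trainable
    transformer backbone, trains all heads jointly under a layer-cost-weighted
    cross-entropy loss, and stops computation per input at the first layer
    whose prediction is confident enough (normalized entropy below a
    threshold) or stable enough (the same class predicted for a run of
    consecutive layers).  The hybrid policy contains entropy-only and
    patience-only early exiting as exact special cases.  Includes budgeted
    (fixed-exit) and dynamic (policy-driven) inference modes, speed-up and
    accuracy evaluation with (tau, patience) grid search, exact parameter
    accounting for published backbone geometries, and seeded synthetic
    corpus and probability-trajectory generators for end-to-end testing
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
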