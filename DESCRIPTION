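Package: erpdecode
Title: Sliding-Window Decoding and Stability Selection for Source-Level ERPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for decoding listener group membership (for example,
    normal hearing versus mild hearing loss) from source-level event-related
    potentials. Builds pseudo-trial feature matrices from single-trial ROI
    time courses (random trial averaging without replacement, baseline
    correction, non-overlapping time-window mean amplitudes,
    z-normalization), classifies groups per time window with grid-searched
    RBF support vector machines for whole-brain and single-hemisphere
    feature sets, and identifies the brain regions that drive group
    segregation via stability selection with randomized L1-penalized
    logistic regression. Ships the 68-region Desikan-Killiany parcellation
    table and a seeded synthetic cohort simulator of P1-N1-P2 evoked
    responses for end-to-end testing without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    glmnet,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
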