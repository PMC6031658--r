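Package: crossmi
Title: Inter-Subject Decoding of Motor Imagery from Simulated MEG and EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for leave-one-subject-out (LOSO) decoding of
    left- versus right-hand motor imagery from multichannel MEG/EEG epochs.
    Implements six inter-subject decoders - three based on common spatial
    patterns (CSP + LDA, per-subject bagged LDA, and regularized CSP with
    generic cross-subject covariances) and three based on sparse logistic
    regression (pooled l1, l1 multi-task, and l2,1 multi-task joint feature
    learning solved by an accelerated proximal-gradient method) - together
    with spatio-spectral decomposition (SSD), within-subject baselines,
    subject-exclusion rules, a binomial chance-level threshold, Friedman and
    post-hoc rank statistics, and a synthetic multi-subject generator of
    sensorimotor-rhythm epochs with lateralized event-related
    desynchronization so the whole study runs end-to-end without any
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    MASS,
    jsonlite,
    withr
Config/testthat/edition: 3
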