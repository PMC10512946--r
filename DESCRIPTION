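Package: wristvel
Title: Continuous Wrist Joint-Velocity Decoding from Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for continuous myoelectric control of a multi-degree-of-freedom
    prosthetic wrist. Maps 8-channel surface electromyography (sEMG) windows to
    pronation-supination or dart-throwing-motion angular velocity with an
    inception-block convolutional regression network, and implements a
    quick-training subject-adaptation protocol (pre-train on a cohort, fine-tune
    on a single trial of a new subject). Includes envelope extraction and
    sliding-window feature generation, marker-based joint-angle kinematics,
    evaluation metrics (RMSE, Pearson correlation, NRMSE, R squared), a
    synthetic multi-subject cohort generator with controllable inter-subject
    domain shift, and a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    signal,
    yaml,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
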