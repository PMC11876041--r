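Package: dynland
Title: Dynamic Survival Prediction with Two-Stage Landmarking Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage dynamic prediction of survival outcomes from
    longitudinal cohort data. Stage one summarizes each subject's covariate
    history up to a landmark time into a fixed-length encoding (baseline or
    last-visit selection, multivariate functional principal component
    analysis with PACE conditional-expectation scores, or an Elman recurrent
    network trained on next-visit prediction and/or a survival likelihood).
    Stage two maps encodings to survival curves with a Cox proportional
    hazards model, a random survival forest, or a discrete-time neural
    network. Four landmarking strategies for training (none, strict, super,
    random per-epoch truncation), a fully parameterized longitudinal-survival
    scenario simulator with ground-truth conditional survival, inverse
    probability of censoring weighted time-dependent AUC and Brier score,
    and a study harness for replicated simulation and cross-validated
    cohort experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    ranger,
    mgcv,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
Config/testthat/edition: 3
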