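Package: oddbold
Title: Auditory Oddball fMRI Simulation and Predictive-Coding Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the predictive-coding analysis of auditory-oddball
    fMRI experiments in which a deviant sound can occur at one of three
    positions of an eight-sound trial, so that subjective expectation
    (the hazard rate of the deviant) varies independently of stimulus
    repetition. The package generates oddball run schedules and BIDS-style
    event tables, simulates analysis-ready BOLD voxel time series under a
    habituation or a prediction-error generative profile, fits first-level
    GLMs with parametric modulation, detects stimulus-specific adaptation
    (SSA) with rank-sum conjunction tests under FDR control, quantifies SSA
    with the SSA index, tests the predictability-response relationship with
    signed-rank contrasts, linear mixed-effects models and per-participant
    Spearman correlations, and compares the habituation and prediction-error
    amplitude models voxel-wise with conjugate linear-model evidence and
    random-effects Bayesian model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    RNifti,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
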