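Package: nocturnet
Title: Balanced Sleep-Stage Scoring with a Two-Branch Attention Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automatic five-class sleep staging (W, N1, N2, N3, REM) from
    five-channel polysomnography (EEG C3/C4, left/right EOG, chin EMG).
    Implements a 1-d attention residual CNN feature extractor with a
    two-branch classifier (an epoch learning branch and a sequential
    learning branch over a context window of neighbouring epochs), trained
    with a transitive schedule that mixes an unweighted epoch loss with a
    class-weighted, gradient-gated sequence loss so that the rare N1 stage
    is rebalanced with minimal damage to overall accuracy.  Includes EDF
    and hypnogram-CSV input/output, the standard PSG preprocessing chain
    (band-pass filtering, amplitude clipping, resampling to 125 Hz),
    hypnogram evaluation metrics (Cohen's kappa, macro-F1,
    stable/transitional decomposition), and a Markov-chain polysomnography
    simulator calibrated to population stage proportions so the whole
    pipeline is testable without access-restricted sleep cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    caret,
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
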