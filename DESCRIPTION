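Package: probselect
Title: Simulation and Model-Based Analysis of Active and Observational
    Probabilistic Feedback Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying feedback-based learning with the probabilistic
    selection task in active and observational (yoked) variants. Provides a
    task and cohort simulator with reinforcement-learning agents, a
    reinforcement-learning model family with choice-induced preference change
    and held-out-phase likelihood fitting with BIC model comparison and latent
    prediction-error extraction, behavioral coding (choice validity,
    win-stay/lose-shift with feedback authenticity, sliding-window learning
    status), synthetic single-trial EEG epoch generation, composite-waveform
    scoring of the feedback-related negativity and error/correct-related
    negativity, and trial-level mixed-effects contrast analysis with
    deviation coding, random-effects backoff and false-discovery-rate
    adjustment.
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
    lhs,
    lme4,
    lmerTest,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    zoo
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
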