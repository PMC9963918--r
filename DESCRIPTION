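Package: replaykit
Title: Decoding-Based Neural Replay Analysis and Reinforcement Learning
    Models for Dual-Environment Sequential Decision Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring sequential neural reactivation ("sequenceness")
    from decoded state probabilities with temporally delayed linear modeling
    (TDLM), training L1-penalized logistic state decoders on sensor epochs,
    fitting model-free, model-based and hybrid Q-learning models to choices in
    a dual-environment two-step task, tracking the rarity of recent experience,
    and linking trial-wise replay strength to planning benefit and memory
    preservation with multilevel regressions, equivalence (TOST) tests and
    permutation-based significance thresholds. Includes a synthetic-data
    generator that produces task schedules, agent behavior, sensor epochs and
    reactivation series with controlled ground truth, so the full pipeline is
    testable end to end without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    broom,
    withr,
    knitr
Config/testthat/edition: 3
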