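Package: rsrl
Title: Risk-Sensitive Reinforcement Learning Models of Serotonin and
    Dopamine in Decision Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tabular reinforcement-learning agents that learn both the
    expected reward (value) and the variance of their reward prediction
    errors (risk), and act on a sign-dependent mean-variance utility in
    which a single weight -- a computational correlate of serotonergic
    tone -- trades value against risk, producing risk aversion for gains
    and risk seeking for losses.  Includes simulators for four behavioural
    paradigms used to study serotonin: a two-armed foraging bandit with a
    contingency reversal, a saccade task with safe and risky juice rewards
    under tryptophan depletion, a delayed-reward patch-clearing task, and
    a deterministic reward/punishment reversal-learning task; plus batch
    running, aggregation, evolutionary parameter search, declarative
    configuration and tabular result output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
VignetteBuilder: knitr
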