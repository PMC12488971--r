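Package: lpengage
Title: Learning-Progress Models of Difficulty, Expectation and Engagement in Games
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how difficulty,
    difficulty-expectation disparity and success drive engagement and
    enjoyment in game-like environments. Provides stochastic environment
    generators (Gaussian number machines and Gaussian-process point
    landscapes), two Bayesian learning agents (a Kalman mean tracker and a
    Gaussian-process function learner) with learning-progress threshold
    stopping rules, negative-binomial engagement regressions with
    participant random intercepts, disparity and level-table measures,
    synthetic behavioral-cohort generators for parameter-recovery studies,
    and a command-line interface for headless pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
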