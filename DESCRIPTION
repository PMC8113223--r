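Package: brivalry
Title: Analysis of Continuous-Report Binocular Rivalry Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for continuous-report binocular rivalry experiments in
    which observers hold one of three keys to report the currently dominant
    percept (e.g. a happy face, a neutral face, or a mixed/piecemeal
    percept). The package parses keypress event logs into dominance
    intervals and reduces each trial to the three standard rivalry
    components: initial percept (IP), onset resolution time (ORT), and
    per-percept cumulative time (CT). It provides the inferential battery
    used in such studies (repeated-measures ANOVA with Greenhouse-Geisser
    correction, Bonferroni-adjusted paired contrasts, default JZS Bayes
    factors, random-intercept logistic regression for initial-percept
    frequencies, Pearson correlations with questionnaire scores), exact
    noncentral-t power analysis for paired designs, a generative simulator
    of rivalry sessions for end-to-end testing and calibration studies, and
    a pipeline that runs the full analysis reproducibly from a config.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    jsonlite,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    knitr,
    optparse,
    pracma,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
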