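Package: dualcap
Title: Dual-Task Capacity Analysis with Attention Operating Characteristics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of dual-task visual psychophysics
    experiments in which observers categorize two briefly flashed letter
    strings. Provides constrained letter-string stimulus generators,
    trial-level simulation of serial, fixed-capacity-parallel and
    independent-parallel observers, rating-ROC accuracy (the nonparametric
    area A_g), attention operating characteristic (AOC) construction with
    quantitative capacity-model predictions and signed distances, estimation
    of the serial top-side processing bias, stimulus-processing trade-off
    analysis, and the inferential machinery used with such designs:
    percentile bootstrap confidence intervals, one-sample and paired t
    tests, Jeffreys-Zellner-Siow Bayes factors, and repeated-measures
    interaction tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
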