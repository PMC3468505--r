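Package: budburst
Title: Process-Based Budburst Phenology Models with Bayesian Calibration
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the spring budburst date of temperate deciduous trees
    from daily mean air temperature with five classical process-based models
    (Thermal Time, Sequential, Parallel, Alternating and Unified), calibrated
    by Metropolis-Hastings random walk under flat priors.  Includes RMSE,
    model-efficiency and AIC model comparison with internal and external
    cross-validation, a temperature-sensitivity analysis of budburst
    advancement under warming, and a synthetic-data generator emulating a
    factorial winter/spring warming chamber experiment on beech, oak and
    birch saplings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
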