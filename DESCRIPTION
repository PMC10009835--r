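Package: sporttraj
Title: Group-Based Trajectory Modelling of Youth Sports Participation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Censored-normal (Tobit-type) group-based trajectory modelling of
    weekly organised-sports participation in school-age children, fitted by an
    EM algorithm with multiple starts. Includes model-selection diagnostics
    (AIC, BIC on observations and on children, average posterior probability of
    assignment, odds of correct classification, child-level k-fold and
    leave-one-out cross-validation), aggregation of weekly SMS-reported session
    counts to monthly panels, sex- and age-stratified motor-performance
    z-score composites with tertiles, multinomial logistic regression of
    trajectory group membership with cluster-robust variance, and a
    longitudinal open-cohort simulator used to validate the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    lubridate,
    jsonlite,
    nnet,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
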