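Package: pantrank
Title: Dominance Rank Trajectories and Siring Success from Dyadic
    Submissive Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring male dominance-rank trajectories from dated
    dyadic submissive interactions (pant-grunts) and relating them to
    personality and reproductive success in long-lived primates. Implements
    a maximum-likelihood Elo rating model in which the update constant and
    each male's hierarchy-entry score are free parameters, daily cardinal
    (win-probability) and ordinal rank series, extraction and validation of
    lifetime rank-trajectory components, questionnaire-based personality
    trait scoring with interrater reliability (ICC), a generalized additive
    mixed model suite for age-by-personality rank analyses with temporal
    cross-validation, and binomial mixed models of siring success compared
    by small-sample corrected AIC. Ships a synthetic-data generator with
    known ground truth for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    lme4,
    mgcv,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
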