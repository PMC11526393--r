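Package: lvforest
Title: Latent Variable Forests for Unbiased Latent Variable Score Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects subgroups of a sample in which a unidimensional graded
    response / ordinal factor model both fits well and has covariate-stable
    parameters, and estimates latent variable scores by averaging empirical
    Bayes modal scores over all such subgroups. Trees are grown with
    score-based (generalized M-fluctuation) parameter instability tests and
    split points that maximise the score statistic; terminal nodes are
    re-fitted with a limited-information polychoric/DWLS estimator and kept
    only if they pass an RMSEA cutoff and a full stability re-assessment.
    Ensembles use bagging and random split selection. Includes a synthetic
    data generator for heterogeneous-subgroup study designs so every stage
    of the pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    withr
Config/testthat/edition: 3
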