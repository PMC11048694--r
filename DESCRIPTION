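Package: skillcurve
Title: Cognito-Motor Sequence Learning Analysis with Hierarchical Bayesian Learning Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing motor sequence learning experiments in which
    participants repeatedly execute a short fixed key-press sequence. Scores
    raw key-press logs into per-trial performance and error classes
    (wrong-key, wrong-order), measures latent cognito-motor abilities
    (working memory, processing speed, psychomotor speed, dexterity) by
    maximum-likelihood confirmatory factor analysis with standard fit
    indices, fits hierarchical Bayesian exponential learning curves with
    correlated individual baseline, asymptote and learning-rate parameters,
    estimates trial-wise standardized performance-ability associations
    controlling for individual learning rates, and models the decline of
    visual control with individual gaze change points. Includes a seeded
    synthetic-study generator so the full pipeline can be exercised and
    validated by parameter-recovery simulation, and a leave-one-out
    (PSIS-LOO) comparison of learning-curve families.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    rjags,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
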