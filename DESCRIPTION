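Package: tmlesoccer
Title: Targeted Learning for the Effect of Substitutions on Soccer Team Distance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Causal-inference toolkit for estimating the average treatment
    effect (ATE) of a soccer substitution in the previous five-minute period
    on the total distance covered by the team in the current period.  Provides
    a structural simulator for the period-level causal model (period index,
    substitutes present, current-period substitution, previous-period
    substitution, bounded team distance), a G-computation plug-in estimator
    built on a parametric linear outcome model, a from-scratch V-fold
    cross-validated super learner (discrete and convex-weighted continuous
    variants) over a pluggable base-learner library, and a targeted maximum
    likelihood estimator (TMLE) with propensity truncation, clever-covariate
    logistic fluctuation on the bounded outcome and efficient-influence-curve
    inference.  An experiment runner reproduces the simulation and
    model-misspecification bias study and the observed-data analysis, with a
    positivity diagnostic and CSV/YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mgcv,
    randomForest,
    rpart,
    pracma,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
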