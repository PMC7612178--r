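Package: msmsim
Title: Simulate and Fit Additive-Hazard Marginal Structural Models for
    Longitudinal Data with Time-Dependent Confounding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates longitudinal treatment, covariate and time-to-event data
    from conditional additive-hazard (or Cox) models with an unmeasured frailty
    and time-dependent confounding, such that the implied marginal structural
    model (MSM) is a known additive hazard model.  Provides stabilized
    inverse-probability-of-treatment weights estimated by pooled logistic
    regression, a weighted Aalen least-squares fitter for the additive MSM with
    counterfactual survival transforms, a Monte-Carlo g-formula oracle that
    marginalizes any conditional generator, intervention-trial truth
    computation, and a replication harness for bias/precision simulation
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    survival,
    optparse,
    withr
Config/testthat/edition: 3
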