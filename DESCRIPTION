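Package: surrosyn
Title: Bayesian Surrogate Endpoint Evaluation with Real-World Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Trial-level surrogate endpoint evaluation combining randomized
    controlled trials with comparative and matched single-arm real-world
    evidence. Provides aggregate-level matching of single-arm studies by a
    weighted scaled-covariate distance, reconstruction of pseudo individual
    patient data from digitized Kaplan-Meier curves and numbers-at-risk
    tables, Bayesian bivariate surrogacy models (the Daniels-Hughes model
    and the product normal formulation of bivariate random-effects
    meta-analysis, with an additive bias-adjusted extension for
    non-randomized designs) fitted by Markov chain Monte Carlo, and
    take-one-out cross-validation of surrogate-based predictions of
    treatment effects on the final outcome.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    tools,
    rjags,
    coda,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
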