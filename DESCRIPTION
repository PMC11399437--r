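Package: vaxcog
Title: Process-Tracing and Hierarchical Prospect-Theory Modelling of Vaccination Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how people inspect and cognitively process
    evidence about vaccines before deciding to accept or refuse vaccination.
    Provides a validated vaccine-evidence table for eight COVID-19 vaccines,
    preprocessing of Mouselab hover-event logs into deliberate-ignorance
    levels and probability-neglect indices, a synthetic-cohort generator with
    known ground truth, a hierarchical Bayesian prospect-theory choice model
    (decision bias, loss aversion, Prelec probability weighting, and a fixed
    0.5 weight for neglected probabilities) fitted with a built-in No-U-Turn
    sampler, supporting hierarchical logistic and ordered-logit regressions,
    posterior diagnostics (split rank-normalized R-hat, highest density
    intervals, balanced predictive accuracy), and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
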