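Package: msmmed
Title: Longitudinal Causal Mediation with Marginal Structural Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Longitudinal causal mediation analysis for three-wave cohort
    studies with a time-varying binary exposure, a time-varying binary
    mediator and a terminal outcome. Fits marginal structural models by
    stabilized inverse-probability-of-treatment, -mediator and -censoring
    weighting, estimates total and direct relative risks by weighted
    modified Poisson regression with robust (sandwich) standard errors,
    and decomposes the total effect into direct and mediated components
    on the excess-relative-risk scale. Includes weight truncation and
    positivity diagnostics, chained-equations multiple imputation with
    Rubin's-rules pooling, deterministic best/worst-case completions for
    informative dropout, bias-corrected and accelerated (BCa) bootstrap
    confidence intervals over the full weighted pipeline, E-values for
    unmeasured confounding, and a calibrated synthetic cohort generator
    with a counterfactual oracle for validating every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    sandwich,
    stats,
    utils
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
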