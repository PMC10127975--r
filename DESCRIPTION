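Package: radgrowth
Title: Tumour Growth and Radiotherapy Response Modelling with Ordinary and
    Fractional Differential Equations
Version: 1.0.0
Authors@R:
    person("Kaye", "Whitcombe", email = "kaye.whitcombe@example.org",
           role = c("aut", "cre"))
Description: Models tumour-volume response to fractionated radiotherapy with
    three classical growth laws (exponential, logistic, exponential-linear)
    extended by a continuous radiation-induced death-rate term built from the
    linear-quadratic survival model and smoothed (tanh) treatment windows.
    Provides Caputo fractional generalizations of the treated models solved by
    the Adams-Bashforth-Moulton predictor-corrector scheme, an impulsive
    (stop-and-restart) comparator with an adaptive Runge-Kutta integrator,
    bounded multistart least-squares parameter fitting, small-sample
    information-criterion model selection (AICc, BIC, Akaike weights, tie-
    averaged rankings), dynamic local relative-sensitivity analysis, a
    synthetic radiotherapy patient-cohort generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
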