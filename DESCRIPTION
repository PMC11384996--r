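Package: hybridsearch
Title: Drift-Diffusion Modelling and Set-Size Statistics for Hybrid Visual Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing hybrid visual search experiments, in which
    observers search a display for any of several targets held in memory.
    Provides trial-level data handling with the standard filtering and
    stimulus-screening rules, a three-parameter Wiener drift-diffusion model
    (analytic first-passage-time densities, trajectory simulation, robust
    likelihood, differential-evolution fitting), a condition-to-parameter
    mapping in which drift depends on memory set size and scene context while
    the decision boundary depends on visual set size, per-participant
    linear/logarithmic set-size regressions with AIC model comparison,
    random-intercept mixed models with likelihood-ratio tests, signal
    detection theory measures (d-prime, criterion c) and Cowan's K, and
    seeded generators that synthesise hybrid-search, change-detection and
    go/no-go trial tables for end-to-end testing of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
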