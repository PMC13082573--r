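Package: ehrdr
Title: Doubly Robust Comparative Effectiveness from Coded EHR Event Streams
Version: 0.1.0
Authors@R:
    person("EHR Methods", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: New-user active-comparator cohort construction from longitudinal
    coded electronic-health-record event streams, high-dimensional baseline
    covariate assembly with two pre-index counting windows, and doubly robust
    (AIPW) estimation of fixed-horizon risk differences and event-free
    survival ratios. Nuisance models are adaptive-LASSO penalized logistic
    regressions, a penalized Lin-Ying additive hazards model, and a
    Kaplan-Meier censoring model used for inverse probability of censoring
    weighting; inference is by nonparametric bootstrap with normal
    approximation. A synthetic EHR generator with a Monte-Carlo oracle for
    the true marginal estimands makes every stage testable without access to
    protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    data.table,
    glmnet,
    survival,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
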