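Package: crtsmall
Title: Analysis of Cluster Randomised Trials with Few Clusters and a Binary Outcome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimators and a Monte-Carlo evaluation engine for two-arm cluster
    randomised trials with a binary outcome and a small number of clusters
    (about 8 to 30). Implements cluster-level analysis on continuity-corrected
    log odds (unweighted and inverse-variance weighted t-tests with
    Kerry-Bland weights), random-intercept logistic mixed models fitted by
    restricted pseudo-likelihood or adaptive Gauss-Hermite quadrature with
    clusters-minus-parameters, Satterthwaite, and Kenward-Roger degrees of
    freedom, and logistic generalised estimating equations with independence
    or exchangeable working correlation and uncorrected, Kauermann-Carroll,
    or Fay-Graubard sandwich covariances. A simulator generates trials under
    a binomial data-generating mechanism with negative-binomial cluster
    sizes and normal, gamma, or uniform cluster effects, and the evaluation
    engine computes standardised bias, standard-error bias, type-one error,
    power, and coverage over scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    parallel,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
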