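Package: permcfa
Title: Permutation Tests of Configural Invariance and Multivariate
    Modification Indices for Multigroup CFA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood estimation of multigroup confirmatory
    factor models with a toolkit for the configural stage of measurement
    invariance testing: permutation tests that refer chi-square, CFI and
    RMSEA to empirical null distributions formed by randomly reassigning
    group labels, score-test (Lagrange multiplier) modification indices in
    both univariate (1-df, per group) and multivariate (g-df, simultaneous
    across groups) form with expected parameter changes, and a Monte Carlo
    harness for Type I error and power studies of these decision rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    parallel,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
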