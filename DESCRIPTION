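Package: fmmm
Title: Covariate-Adjusted Functional Mixed Membership Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian mixed membership models for functional data in which
    each observed curve is a convex combination of K latent functional
    features whose means depend linearly on scalar covariates. Features are
    represented in an equidistant-knot B-spline basis with a truncated
    multivariate Karhunen-Loeve expansion of the joint covariance, and the
    posterior is explored by a Gibbs sampler with Metropolis-Hastings
    allocation updates and optional tempered transitions. Includes
    identifiability diagnostics, label-switching and separability
    post-processing, covariance eigen-analysis, information criteria and
    conditional predictive ordinates for choosing the number of features,
    and a synthetic-data generator for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    splines,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
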