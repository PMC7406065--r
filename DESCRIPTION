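Package: bottomup
Title: Bottom-Up Small-Area Population Density Estimation from Surveys
    and Geospatial Covariates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates village-level population density between census
    years by combining a household survey with geospatial covariates.
    Survey-derived village densities are modelled with a weighted Poisson
    pseudo-likelihood, covariates are selected by an L1 (LASSO) penalty
    solved by iteratively reweighted cyclic coordinate descent with the
    penalty level chosen by k-fold cross-validation, predictions come
    from an unpenalized refit on the selected support, and non-ignorable
    village selection is corrected with probit-based inverse-probability
    weights.  Includes a synthetic scenario generator emulating a
    national census, a two-stage stratified household survey, accuracy
    and coefficient-of-variation evaluation, and top-down dasymetric
    redistribution baselines for census-staleness experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
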