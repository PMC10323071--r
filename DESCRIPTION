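Package: saele
Title: Small-Area Estimation of Life Expectancy and Spatial Inequities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for estimating life expectancy in small areas of a
    city and quantifying its socioeconomic inequities. Builds single-year
    population denominators from census proportions and penalized composite
    link model (PCLM) graduation of grouped projections, estimates age- and
    sex-specific mortality rates with a Bayesian spatial TOPALS Poisson
    model fitted by adaptive random-walk Metropolis, converts each posterior
    draw into a single-age life table, and summarises inequities across
    areas via percentile gaps, decile scoring, the slope index of inequality
    with Rubin-pooled uncertainty, and a composite socioeconomic Z-score.
    Includes a synthetic-city generator with known ground truth for
    parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
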