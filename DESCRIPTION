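Package: dynocc
Title: Multi-Season Occupancy Analysis of Landscape-Scale Acoustic
    Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested workflow for landscape-scale, temporally dynamic
    occupancy analysis of grid-cell acoustic monitoring data such as the
    North American Bat Monitoring Program (NABat) design. Provides a
    synthetic-data generator emulating the survey structure (stationary and
    mobile survey nights on 10x10 km cells across ecoregions, two seasons,
    colonization-extinction dynamics), categorical-raster landscape metrics
    (percent cover, edge density, contagion), a Pearson correlation screen
    and covariate standardization, a hierarchical Bayesian multi-season
    occupancy model with imperfect detection fit by Metropolis-within-Gibbs
    MCMC with a closed-form marginal likelihood, Brooks-Gelman-Rubin
    convergence diagnostics, WAIC model ranking with relative likelihoods
    and weights, region-constrained k-fold cross-validated AUC, predicted
    occupancy grids, and colonization/extinction/turnover estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
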