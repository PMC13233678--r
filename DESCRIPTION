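Package: canopyn
Title: Canopy Nitrogen Estimation from Hyperspectral Reflectance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation of maize canopy nitrogen content (mg/g dry weight)
    from 400-1000 nm hyperspectral reflectance. Implements
    Grunwald-Letnikov fractional-order derivative spectral transforms,
    genetic-algorithm and successive-projections wavelength selection and
    their hybrid, a 24-index vegetation-index library screened by seven
    criteria and aggregated by overall-difference combination assessment
    (ODCA) rank fusion, exhaustive two- and three-band spectral-index
    optimization over the fractional-order grid, a stacked ensemble
    regressor (gradient-boosted trees and ridge bases with a Bayesian
    ridge meta-learner), Shapley-value attribution with meta-weighted
    fusion, and a phenomenological canopy reflectance simulator with a
    known nitrogen-spectrum link for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    jsonlite,
    yaml,
    xgboost,
    e1071,
    ranger,
    glmnet
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'utils.R'
    'learners.R'
    'spectra-io.R'
    'synthetic-canopy.R'
    'fod.R'
    'band-selection.R'
    'vegetation-indices.R'
    'index-search.R'
    'modeling.R'
    'interpret.R'
    'pipeline.R'
    'canopyn-package.R'
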