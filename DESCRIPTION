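Package: cetadens
Title: Cetacean Density Models from Visual Line-Transect and Passive Acoustic Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating cetacean densities from shipboard
    line-transect visual surveys (distance sampling with detection-function
    selection by AIC) and from fixed passive acoustic monitoring sites
    (a group-counting estimator on daily bins of 5-minute detection windows),
    attaching environmental covariates including distances to mesoscale
    eddies detected from sea-surface-height fields, and fitting species
    distribution models on acoustic-only, visual-only, or joint data with two
    frameworks: Tweedie generalized additive models with shrinkage smooths,
    and averaged ensembles of single-hidden-layer neural networks.
    Predictions outside the training covariate ranges are masked, model
    skill is compared by root-mean-square error, and a synthetic-data
    generator with a known density surface supports end-to-end parameter
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1), mgcv
Imports:
    nnet,
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
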