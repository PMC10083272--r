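Package: anthomap
Title: Hyperspectral Prediction and Mapping of Anthocyanin Content in Mulberry Fruit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for non-destructive estimation of
    anthocyanin content (mg/g, cyanidin-3-glucoside equivalents) in
    mulberry fruit from visible/near-infrared hyperspectral images.
    Provides reflectance calibration against white and dark references,
    rule-based fruit segmentation with stalk removal, standard normal
    variate preprocessing, three spectral variable-reduction engines
    (successive projections algorithm, competitive adaptive reweighted
    sampling, stacked auto-encoder), extreme learning machine and
    least-squares support vector machine regression with genetic-algorithm
    hyperparameter optimization, pH-differential wet-chemistry reference
    computation, per-pixel prediction mapping, and a synthetic
    hyperspectral scene generator emulating a two-variety, three-maturity
    study design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    Rcpp,
    jsonlite,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
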