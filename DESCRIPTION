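Package: flute
Title: Nonparametric U-Statistic Tests of Dependence in Functional
    Linear Models
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tests whether the regression operator of a functional
    linear model equals an assigned structure (in particular, zero,
    i.e. no dependence between a functional predictor and a scalar or
    functional response) without estimating the covariance operator of
    the predictor.  The test statistic is a degenerate U-statistic over
    quadruples of subjects, standardized by unbiased trace estimators
    of the squared covariance operators of the predictor and of the
    residual process, and calibrated by its normal limit.  Includes
    orthonormal basis projection of densely observed curves, an exact
    O(n^2) reduction of the quadruple-average statistic, asymptotic
    power calculations, synthetic-data generators with moving-average
    factor loadings, and a Monte-Carlo driver for size and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, splines
Suggests: testthat (>= 3.0.0), yaml, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
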