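Package: semdif
Title: Item Bias Detection in Ordinal Questionnaires by Structural
    Equation Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects uniform and nonuniform item bias (differential item
    functioning) in ordinal questionnaire items with two structural
    equation modeling procedures: a multigroup common-factor approach and
    a multidimensional restricted factor analysis approach with exogenous
    violator variables.  Implements the two-stage estimation for discrete
    data (thresholds and polychoric/polyserial correlations with an
    influence-function asymptotic covariance, then diagonally weighted
    least squares fitting of factor models with mean structure), WLS
    chi-square and RMSEA fit evaluation, greedy iterative bias searches
    with chi-square difference tests, effect-size quantification of
    detected bias, and bias-adjusted estimation of true latent group
    differences and associations.  Includes a graded-response synthetic
    data generator with configurable injected bias, and an
    ordinal-logistic-regression baseline for cross-method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'bvnorm.R'
    'AllClasses.R'
    'AllGenerics.R'
    'synthgen.R'
    'thresholds.R'
    'polychoric.R'
    'stage1.R'
    'semcore-models.R'
    'semcore-fit.R'
    'difmg.R'
    'difmd.R'
    'baseline.R'
    'io.R'
    'appshell.R'
    'semdif-package.R'
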