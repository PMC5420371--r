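#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("characterOrNULL", c("character", "NULL"))

#' Generating specification for ordinal item-response data
#'
#' Describes a graded common-factor population: items load on one or two
#' correlated normal factors, underlying continuous responses are formed as
#' intercept + loading * factor + injected bias terms + normal residual, and
#' are then discretized at fixed thresholds into ordered categories.
#' Group differences enter through per-group factor means/SDs and per-group
#' loadings/intercepts; "violators" are observed covariates (binary or
#' continuous) that may carry injected uniform (additive) or nonuniform
#' (loading, i.e. violator-by-factor interaction) item bias.
#'
#' @slot nItems number of items.
#' @slot nCategories number of ordered response categories per item.
#' @slot nGroups 1 or 2 (reference/focal).
#' @slot itemFactor integer vector mapping each item to a factor.
#' @slot loadings numeric matrix, nGroups x nItems.
#' @slot intercepts numeric matrix, nGroups x nItems.
#' @slot residualSds numeric vector of residual SDs, length nItems.
#' @slot thresholds list of length nItems; each element the (nCategories - 1)
#'   strictly increasing cut points.
#' @slot factorMeans,factorSds numeric matrices, nGroups x nFactors.
#' @slot factorCorr correlation between the two factors (ignored with one).
#' @slot violators list of violator definitions, each a list with elements
#'   \code{name}, \code{kind} ("binary"/"continuous"), \code{prevalence} or
#'   \code{mean}/\code{sd}, and \code{corFactors} (correlation of the
#'   violator's latent layer with each factor; for a binary violator the
#'   observed 0/1 indicator's correlation with the factor is attenuated by
#'   the factor \eqn{\phi(z_p)/\sqrt{p(1-p)}} of the thresholding).
#' @slot difDefs data.frame with columns item, violator, type
#'   ("uniform"/"nonuniform"), size.
#' @slot itemNames character labels.
#' @export
setClass("GeneratorSpec", representation(
  nItems = "integer",
  nCategories = "integer",
  nGroups = "integer",
  itemFactor = "integer",
  loadings = "matrix",
  intercepts = "matrix",
  residualSds = "numeric",
  thresholds = "list",
  factorMeans = "matrix",
  factorSds = "matrix",
  factorCorr = "numeric",
  violators = "list",
  difDefs = "data.frame",
  itemNames = "character"
))

setValidity("GeneratorSpec", function(object) {
  msg <- character(0)
  p <- object@nItems
  if (length(object@itemFactor) != p) msg <- c(msg, "itemFactor length != nItems")
  if (ncol(object@loadings) != p || ncol(object@intercepts) != p)
    msg <- c(msg, "loadings/intercepts must have nItems columns")
  if (length(object@residualSds) != p) msg <- c(msg, "residualSds length != nItems")
  if (any(object@residualSds <= 0)) msg <- c(msg, "residualSds must be > 0")
  if (any(object@factorSds <= 0)) msg <- c(msg, "factorSds must be > 0")
  if (abs(object@factorCorr) >= 1) msg <- c(msg, "|factorCorr| must be < 1")
  if (length(object@thresholds) != p) msg <- c(msg, "thresholds list length != nItems")
  for (i in seq_len(p)) {
    tau <- object@thresholds[[i]]
    if (length(tau) != object@nCategories - 1L)
      msg <- c(msg, sprintf("item %d: need %d thresholds", i, object@nCategories - 1L))
    if (any(diff(tau) <= 0))
      msg <- c(msg, sprintf("item %d: thresholds not strictly increasing", i))
  }
  vnames <- vapply(object@violators, function(v) v$name, character(1))
  if (object@nGroups == 2L) vnames <- c(vnames, "group")
  if (nrow(object@difDefs)) {
    if (any(object@difDefs$item < 1 | object@difDefs$item > p))
      msg <- c(msg, "difDefs reference nonexistent items")
    if (!all(object@difDefs$violator %in% vnames))
      msg <- c(msg, "difDefs reference nonexistent violators")
    if (!all(object@difDefs$type %in% c("uniform", "nonuniform")))
      msg <- c(msg, "difDefs type must be uniform or nonuniform")
  }
  if (length(msg)) msg else TRUE
})

#' Ordinal item-response dataset
#'
#' Respondents-by-items integer response matrix (categories 0..K-1), with an
#' optional binary group label and named numeric covariate columns.
#'
#' @slot responses integer matrix, respondents x items.
#' @slot group factor with two levels, or NULL.
#' @slot covariates data.frame of per-respondent numeric covariates.
#' @slot itemNames character labels for the items.
#' @slot nCategories number of response categories.
#' @export
setClass("OrdinalDataset", representation(
  responses = "matrix",
  group = "ANY",
  covariates = "data.frame",
  itemNames = "character",
  nCategories = "integer"
))

setValidity("OrdinalDataset", function(object) {
  msg <- character(0)
  r <- object@responses
  ok <- is.na(r) | (r == round(r) & r >= 0 & r <= object@nCategories - 1L)
  if (!all(ok)) msg <- c(msg, "responses must be integers in [0, K-1] or NA")
  if (!is.null(object@group)) {
    if (nlevels(factor(object@group)) != 2L)
      msg <- c(msg, "group must take exactly two values")
    if (length(object@group) != nrow(r))
      msg <- c(msg, "group length != number of respondents")
  }
  if (nrow(object@covariates) && nrow(object@covariates) != nrow(r))
    msg <- c(msg, "covariates rows != number of respondents")
  if (length(object@itemNames) != ncol(r))
    msg <- c(msg, "itemNames length != number of items")
  if (length(msg)) msg else TRUE
})

#' Stage 1 result: thresholds, correlations and their asymptotic covariance
#'
#' The bridge between the underlying-variable model and the factor-model
#' stage: pooled (equal-across-group) thresholds, polychoric/polyserial
#' correlations per group, focal-group underlying means/SDs relative to the
#' standardized reference group, per-pair bivariate-normality RMSEA
#' diagnostics, and the stacked moment vector with its influence-function
#' asymptotic covariance.
#'
#' @slot design "single_group" or "multigroup".
#' @slot itemNames,covariateNames labels.
#' @slot thresholds list per item of cut points (pooled across groups).
#' @slot correlations list per group of correlation matrices over the
#'   underlying item variables (and standardized covariates, single-group).
#' @slot underlyingMeans,underlyingSds matrices nGroups x nItems; the
#'   reference (first) row is 0 / 1 by the identification convention.
#' @slot pairRmsea matrix of per-pair bivariate-normality RMSEA values
#'   (max over groups).
#' @slot flaggedPairs character matrix of pairs with RMSEA > 0.1.
#' @slot moments named numeric vector: the stacked stochastic moments fitted
#'   in the second stage.
#' @slot acov asymptotic covariance (N * var) of \code{moments}.
#' @slot nPerGroup observation counts per group.
#' @slot groupLevels labels of the reference and focal group.
#' @export
setClass("Stage1Result", representation(
  design = "character",
  itemNames = "character",
  covariateNames = "character",
  thresholds = "list",
  correlations = "list",
  underlyingMeans = "matrix",
  underlyingSds = "matrix",
  pairRmsea = "matrix",
  flaggedPairs = "matrix",
  moments = "numeric",
  acov = "matrix",
  nPerGroup = "integer",
  groupLevels = "character"
))

setValidity("Stage1Result", function(object) {
  msg <- character(0)
  q <- length(object@moments)
  if (!isTRUE(all.equal(dim(object@acov), c(q, q))))
    msg <- c(msg, "acov dimension must match the moment vector")
  if (q && max(abs(object@acov - t(object@acov))) > 1e-8)
    msg <- c(msg, "acov must be symmetric")
  for (R in object@correlations) {
    if (max(abs(diag(R) - 1)) > 1e-8) msg <- c(msg, "correlation diagonals must be 1")
    if (any(abs(R) > 1 + 1e-8)) msg <- c(msg, "correlations must lie in [-1, 1]")
  }
  if (nrow(object@underlyingMeans)) {
    if (max(abs(object@underlyingMeans[1L, ])) > 1e-10 ||
        max(abs(object@underlyingSds[1L, ] - 1)) > 1e-10)
      msg <- c(msg, "reference group must be standardized (means 0, SDs 1)")
  }
  if (length(msg)) msg else TRUE
})

#' Factor-model specification with mean structure
#'
#' Declarative pattern of a multigroup one-factor model or a single-group
#' multidimensional (restricted factor analysis) model.  Two families are
#' supported: \code{"mg"} (two groups, one factor; cross-group equality of
#' loadings/intercepts with per-item exemptions) and \code{"md"} (one group,
#' one or two correlated factors, optional exogenous violators whose
#' violator-to-item direct effects are fixed at zero unless freed).
#'
#' @slot family "mg" or "md".
#' @slot variant for "mg": "measurement" (no across-group constraints, both
#'   groups standardized) or "constrained" (loadings/intercepts equal across
#'   groups, focal factor mean/variance free).
#' @slot nItems,nGroups counts.
#' @slot itemFactor factor assignment of items (md family).
#' @slot freeNu,freeLambda item indices exempted from cross-group equality
#'   (mg "constrained" variant).
#' @slot violatorNames exogenous violators (md family).
#' @slot freeDirect two-column matrix (item, violator index) of direct
#'   effects freed from zero (md family).
#' @slot thetaEqual constrain residual variances equal across groups (mg
#'   "constrained" variant; FALSE by default — residual differences are not
#'   treated as bias, and the free-theta pattern reproduces the standard df
#'   arithmetic).
#' @slot itemNames labels.
#' @export
setClass("ModelSpec", representation(
  family = "character",
  variant = "character",
  nItems = "integer",
  nGroups = "integer",
  itemFactor = "integer",
  freeNu = "integer",
  freeLambda = "integer",
  violatorNames = "character",
  freeDirect = "matrix",
  thetaEqual = "logical",
  itemNames = "character"
))

setValidity("ModelSpec", function(object) {
  msg <- character(0)
  if (!object@family %in% c("mg", "md")) msg <- c(msg, "family must be 'mg' or 'md'")
  if (object@family == "mg" && !object@variant %in% c("measurement", "constrained"))
    msg <- c(msg, "mg variant must be 'measurement' or 'constrained'")
  p <- object@nItems
  if (any(object@freeNu < 1 | object@freeNu > p) ||
      any(object@freeLambda < 1 | object@freeLambda > p))
    msg <- c(msg, "freed parameter indices out of range")
  if (nrow(object@freeDirect)) {
    if (any(object@freeDirect[, 1L] < 1 | object@freeDirect[, 1L] > p) ||
        any(object@freeDirect[, 2L] < 1 |
            object@freeDirect[, 2L] > length(object@violatorNames)))
      msg <- c(msg, "freeDirect indices out of range")
  }
  if (length(msg)) msg else TRUE
})

#' Result of a DWLS factor-model fit
#'
#' @slot model the fitted \linkS4class{ModelSpec}.
#' @slot estimates named parameter estimates (free and derived).
#' @slot robustSes named robust (sandwich) standard errors of free parameters.
#' @slot discrepancy minimized DWLS discrepancy value.
#' @slot chisq full-weight WLS chi-square evaluated at the DWLS estimates.
#' @slot df model degrees of freedom.
#' @slot pValue exact-fit p value.
#' @slot rmsea,rmseaCi RMSEA point estimate and 90 percent interval.
#' @slot converged logical convergence flag.
#' @slot nTotal,nGroups sample bookkeeping.
#' @slot residuals named moment residuals (data minus implied).
#' @slot implied named model-implied moments at the solution.
#' @export
setClass("FitResult", representation(
  model = "ModelSpec",
  estimates = "numeric",
  robustSes = "numeric",
  discrepancy = "numeric",
  chisq = "numeric",
  df = "integer",
  pValue = "numeric",
  rmsea = "numeric",
  rmseaCi = "numeric",
  converged = "logical",
  nTotal = "integer",
  nGroups = "integer",
  residuals = "numeric",
  implied = "numeric",
  jacobian = "matrix",
  traceUG = "numeric"
))

setValidity("FitResult", function(object) {
  msg <- character(0)
  if (object@df < 0L) msg <- c(msg, "df must be >= 0")
  if (length(object@rmsea) && object@rmsea < 0) msg <- c(msg, "rmsea must be >= 0")
  if (length(object@rmseaCi) == 2L && length(object@rmsea) &&
      (object@rmseaCi[1L] > object@rmsea + 1e-8 ||
       object@rmseaCi[2L] < object@rmsea - 1e-8))
    msg <- c(msg, "rmsea must lie inside its confidence interval")
  if (length(msg)) msg else TRUE
})

#' Report of an iterative item-bias search
#'
#' @slot procedure "multigroup" or "multidimensional".
#' @slot findings data.frame of detected biases: item, violator, type,
#'   chisqDiff, dfDiff, p, effectSize, important, step.
#' @slot modelTrail named list of \linkS4class{FitResult}s (Measurement,
#'   No-Item-Bias, each accepted intermediate, Final).
#' @slot trueDifference data.frame of latent group differences (multigroup):
#'   context, d, se, p.
#' @slot associations data.frame of latent correlations (multidimensional):
#'   varA, varB, r, p, context ("unadjusted"/"adjusted").
#' @slot flaggedPairs pairs failing the Stage 1 normality screen.
#' @slot log character vector auditing every search decision.
#' @export
setClass("DifReport", representation(
  procedure = "character",
  findings = "data.frame",
  modelTrail = "list",
  trueDifference = "data.frame",
  associations = "data.frame",
  flaggedPairs = "matrix",
  log = "character"
))

setValidity("DifReport", function(object) {
  msg <- character(0)
  f <- object@findings
  if (nrow(f)) {
    if (any(f$p >= 0.001)) msg <- c(msg, "recorded findings must have p < .001")
    if (any(f$important & abs(f$effectSize) <= .semdifImportance(object@procedure)))
      msg <- c(msg, "important findings must exceed the effect-size threshold")
  }
  if (length(msg)) msg else TRUE
})

.semdifImportance <- function(procedure) {
  if (identical(procedure, "multidimensional")) 0.1 else 0.2
}
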