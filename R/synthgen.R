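#' @include AllClasses.R
NULL

#' Construct a generating specification
#'
#' Low-level constructor for \linkS4class{GeneratorSpec}; most users will
#' start from \code{\link{makeHadsLikeSpec}} and modify the result.
#'
#' @param nItems,nCategories,nGroups counts.
#' @param itemFactor integer factor assignment per item.
#' @param loadings,intercepts per-group item parameters; a vector is recycled
#'   to all groups.
#' @param residualSds residual SDs per item; defaults to
#'   \code{sqrt(1 - loading^2)} of the first group so underlying variables
#'   have unit total variance.
#' @param thresholds list of per-item cut points.
#' @param factorMeans,factorSds per-group factor means/SDs
#'   (nGroups x nFactors).
#' @param factorCorr correlation between the two factors.
#' @param violators list of violator definitions (see
#'   \linkS4class{GeneratorSpec}).
#' @param difDefs data.frame of injected biases (item, violator, type, size).
#' @param itemNames labels.
#' @return a validated \linkS4class{GeneratorSpec}.
#' @export
makeGeneratorSpec <- function(nItems, nCategories = 4L, nGroups = 1L,
                              itemFactor = rep(1L, nItems),
                              loadings, intercepts = 0, residualSds = NULL,
                              thresholds, factorMeans = NULL, factorSds = NULL,
                              factorCorr = 0, violators = list(),
                              difDefs = NULL,
                              itemNames = paste0("item", seq_len(nItems))) {
  nItems <- as.integer(nItems)
  m <- max(itemFactor)
  toMat <- function(x) {
    if (is.matrix(x)) x else matrix(rep_len(x, nItems), nGroups, nItems, byrow = TRUE)
  }
  loadings <- toMat(loadings)
  intercepts <- toMat(intercepts)
  if (is.null(residualSds)) residualSds <- sqrt(pmax(1 - loadings[1L, ]^2, 0.05))
  if (is.null(factorMeans)) factorMeans <- matrix(0, nGroups, m)
  if (is.null(factorSds)) factorSds <- matrix(1, nGroups, m)
  if (!is.matrix(factorMeans)) factorMeans <- matrix(rep_len(factorMeans, nGroups * m), nGroups, m)
  if (!is.matrix(factorSds)) factorSds <- matrix(rep_len(factorSds, nGroups * m), nGroups, m)
  if (is.null(difDefs))
    difDefs <- data.frame(item = integer(0), violator = character(0),
                          type = character(0), size = numeric(0))
  new("GeneratorSpec", nItems = nItems, nCategories = as.integer(nCategories),
      nGroups = as.integer(nGroups), itemFactor = as.integer(itemFactor),
      loadings = loadings, intercepts = intercepts,
      residualSds = as.numeric(residualSds), thresholds = thresholds,
      factorMeans = factorMeans, factorSds = factorSds,
      factorCorr = as.numeric(factorCorr), violators = violators,
      difDefs = difDefs, itemNames = itemNames)
}

#' Ready-made generating scenarios
#'
#' Populated \linkS4class{GeneratorSpec}s emulating a HADS-like instrument:
#' four ordered response categories, seven items per subscale, loadings
#' between 0.6 and 0.8 on a unit-variance underlying scale, mildly skewed
#' category cut points as is typical for symptom items.  The two-factor
#' scenario uses 14 items on two factors correlated 0.8 with a binary and a
#' continuous violator; the two-group scenarios use equal measurement
#' parameters in both groups with configurable injected bias on one item.
#'
#' @param scenario one of \code{"one_factor_7"}, \code{"two_factor_14"},
#'   \code{"no_dif"}, \code{"uniform_dif"}, \code{"nonuniform_dif"}.
#' @param difItem item receiving injected bias (scenarios *_dif).
#' @param difSize bias size on the underlying scale: the uniform shift, or
#'   the loading increment for nonuniform bias.
#' @param groupMeanDiff focal-group latent mean (two-group scenarios);
#'   reference is 0.
#' @return a \linkS4class{GeneratorSpec}.
#' @export
makeHadsLikeSpec <- function(scenario, difItem = 3L, difSize = NULL,
                             groupMeanDiff = -0.3) {
  valid <- c("one_factor_7", "two_factor_14", "no_dif", "uniform_dif",
             "nonuniform_dif")
  if (!is.character(scenario) || length(scenario) != 1L || !scenario %in% valid)
    stop("unknown scenario; valid scenarios are: ", paste(valid, collapse = ", "))
  lam7 <- c(0.7, 0.6, 0.8, 0.7, 0.6, 0.8, 0.7)
  tau7 <- lapply(seq(-0.3, 0.3, length.out = 7), function(s) c(-0.4, 0.5, 1.3) + s)
  switch(scenario,
    one_factor_7 = makeGeneratorSpec(7L, loadings = lam7, thresholds = tau7),
    two_factor_14 = makeGeneratorSpec(
      14L, itemFactor = rep(1:2, each = 7L), loadings = rep(lam7, 2),
      thresholds = c(tau7, tau7), factorCorr = 0.8,
      violators = list(
        list(name = "gender", kind = "binary", prevalence = 0.41,
             corFactors = c(-0.16, -0.04)),
        list(name = "age", kind = "continuous", mean = 50, sd = 18,
             corFactors = c(-0.24, 0.01))),
      itemNames = paste0("item", 1:14)),
    no_dif = makeGeneratorSpec(7L, nGroups = 2L, loadings = lam7,
                               thresholds = tau7),
    uniform_dif = makeGeneratorSpec(
      7L, nGroups = 2L, loadings = lam7, thresholds = tau7,
      factorMeans = matrix(c(0, groupMeanDiff), 2L, 1L),
      difDefs = data.frame(item = as.integer(difItem), violator = "group",
                           type = "uniform",
                           size = if (is.null(difSize)) 0.5 else difSize)),
    nonuniform_dif = makeGeneratorSpec(
      7L, nGroups = 2L, loadings = lam7, thresholds = tau7,
      factorMeans = matrix(c(0, groupMeanDiff), 2L, 1L),
      difDefs = data.frame(item = as.integer(difItem), violator = "group",
                           type = "nonuniform",
                           size = if (is.null(difSize)) 0.3 else difSize))
  )
}

# joint latent correlation matrix over (factors, violator latents)
.latentCorr <- function(spec) {
  m <- max(spec@itemFactor)
  q <- length(spec@violators)
  C <- diag(m + q)
  if (m == 2L) C[1L, 2L] <- C[2L, 1L] <- spec@factorCorr
  for (k in seq_len(q)) {
    cf <- rep_len(spec@violators[[k]]$corFactors, m)
    C[seq_len(m), m + k] <- C[m + k, seq_len(m)] <- cf
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8)
    stop("violator/factor correlation structure is not positive definite")
  C
}

#' Simulate ordinal item responses from a generating specification
#'
#' Draws factor scores and violator variables from a joint multivariate
#' normal latent layer (binary violators by thresholding at their prevalence),
#' forms continuous underlying responses
#' \eqn{y* = \nu + \lambda T + \sum \delta V + \sum \delta V T + \epsilon}
#' with the injected uniform/nonuniform bias terms, and discretizes at the
#' item thresholds (category = number of thresholds exceeded).
#'
#' @param spec a \linkS4class{GeneratorSpec}.
#' @param nPerGroup respondents per group (total n for single-group specs).
#' @param seed integer seed; the draw is fully deterministic given it.
#' @param returnLatent if TRUE also return the continuous underlying
#'   responses and factor scores, for verifying injected bias directly.
#' @return an \linkS4class{OrdinalDataset}, or, with
#'   \code{returnLatent = TRUE}, a list with elements \code{data},
#'   \code{latent} (underlying continuous responses) and \code{factors}.
#' @export
simulateOrdinal <- function(spec, nPerGroup, seed, returnLatent = FALSE) {
  stopifnot(is(spec, "GeneratorSpec"))
  validObject(spec)
  if (nPerGroup < 1) stop("nPerGroup must be >= 1")
  set.seed(as.integer(seed))
  G <- spec@nGroups
  p <- spec@nItems
  m <- max(spec@itemFactor)
  q <- length(spec@violators)
  n <- as.integer(nPerGroup) * G
  groupIdx <- rep(seq_len(G), each = as.integer(nPerGroup))

  Z <- MASS::mvrnorm(n, mu = rep(0, m + q), Sigma = .latentCorr(spec))
  Z <- matrix(Z, nrow = n)
  # factor scores: per-group location/scale
  Tm <- matrix(0, n, m)
  for (j in seq_len(m))
    Tm[, j] <- spec@factorMeans[groupIdx, j] + spec@factorSds[groupIdx, j] * Z[, j]
  # violator values
  V <- matrix(0, n, q)
  vnames <- character(q)
  for (k in seq_len(q)) {
    v <- spec@violators[[k]]
    vnames[k] <- v$name
    V[, k] <- if (identical(v$kind, "binary")) {
      as.numeric(Z[, m + k] > qnorm(1 - v$prevalence))
    } else {
      v$mean + v$sd * Z[, m + k]
    }
  }
  # bias terms use violators on an interpretable scale: the 0/1 indicator
  # for binary violators (size = underlying shift of the V = 1 subgroup)
  # and the unit-SD scale for continuous ones (size = standardized effect)
  violValue <- function(name) {
    if (identical(name, "group") && G == 2L) return(as.numeric(groupIdx == 2L))
    k <- match(name, vnames)
    if (identical(spec@violators[[k]]$kind, "binary")) V[, k] else Z[, m + k]
  }

  lat <- matrix(0, n, p)
  for (i in seq_len(p)) {
    f <- spec@itemFactor[i]
    y <- spec@intercepts[groupIdx, i] + spec@loadings[groupIdx, i] * Tm[, f]
    dd <- spec@difDefs[spec@difDefs$item == i, , drop = FALSE]
    for (d in seq_len(nrow(dd))) {
      v <- violValue(dd$violator[d])
      y <- y + if (identical(dd$type[d], "uniform")) dd$size[d] * v
               else dd$size[d] * v * Tm[, f]
    }
    lat[, i] <- y + rnorm(n, sd = spec@residualSds[i])
  }
  resp <- matrix(0L, n, p, dimnames = list(NULL, spec@itemNames))
  for (i in seq_len(p))
    resp[, i] <- findInterval(lat[, i], spec@thresholds[[i]])

  covdf <- as.data.frame(V)
  names(covdf) <- vnames
  ds <- new("OrdinalDataset", responses = resp,
            group = if (G == 2L) factor(c("ref", "focal")[groupIdx],
                                        levels = c("ref", "focal")) else NULL,
            covariates = covdf, itemNames = spec@itemNames,
            nCategories = spec@nCategories)
  if (returnLatent) list(data = ds, latent = lat, factors = Tm) else ds
}
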