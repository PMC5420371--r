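#' @include bvnorm.R thresholds.R
NULL

# cell probabilities of an R x C table under the bivariate normal model:
# corners at (-Inf, tauRow, Inf) x (-Inf, tauCol, Inf)
.cellProbs <- function(rho, tauRow, tauCol) {
  a <- c(-Inf, tauRow, Inf)
  b <- c(-Inf, tauCol, Inf)
  P <- matrix(pbvnorm(rep(a, times = length(b)), rep(b, each = length(a)), rho),
              length(a), length(b))
  pr <- P[-1L, -1L, drop = FALSE] - P[-length(a), -1L, drop = FALSE] -
    P[-1L, -length(b), drop = FALSE] + P[-length(a), -length(b), drop = FALSE]
  pmax(pr, 1e-12)
}

# d pi / d rho, cellwise: differences of the bivariate normal density at the
# cell corners (density is zero at infinite corners)
.cellProbsDrho <- function(rho, tauRow, tauCol) {
  a <- c(-Inf, tauRow, Inf)
  b <- c(-Inf, tauCol, Inf)
  D <- matrix(dbvnorm(rep(a, times = length(b)), rep(b, each = length(a)), rho),
              length(a), length(b))
  D[-1L, -1L, drop = FALSE] - D[-length(a), -1L, drop = FALSE] -
    D[-1L, -length(b), drop = FALSE] + D[-length(a), -length(b), drop = FALSE]
}

# mean score d/d rho of the multinomial log-likelihood, as a function of the
# cell proportion matrix (used both for estimation and influence functions)
.polychoricScore <- function(rho, tauRow, tauCol, props) {
  sum(props * .cellProbsDrho(rho, tauRow, tauCol) /
        .cellProbs(rho, tauRow, tauCol))
}

#' Two-step polychoric correlation
#'
#' Maximizes the bivariate-normal multinomial likelihood of a contingency
#' table over the latent correlation, with the thresholds held fixed (the
#' standard two-step estimator: thresholds come from the univariate margins
#' first).  The estimate is confined to [-0.999, 0.999]; hitting that
#' boundary (e.g. a perfectly concordant table) sets the \code{boundary}
#' flag.
#'
#' @param tab R x C contingency table of counts (rows = first item).
#' @param tauRow,tauCol fixed thresholds of the two margins (lengths R-1 and
#'   C-1).
#' @param seTheta if TRUE (default) compute the model-based standard error
#'   from the observed information.
#' @return list with elements \code{rho}, \code{se}, \code{boundary},
#'   \code{loglik}, \code{n}.
#' @export
estimatePolychoric <- function(tab, tauRow, tauCol, seTheta = TRUE) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  if (n <= 0) stop("contingency table has no observations")
  stopifnot(nrow(tab) == length(tauRow) + 1L, ncol(tab) == length(tauCol) + 1L)
  ll <- function(rho) sum(tab * log(.cellProbs(rho, tauRow, tauCol)))
  opt <- stats::optimize(ll, c(-0.999, 0.999), maximum = TRUE, tol = 1e-7)
  rho <- opt$maximum
  boundary <- FALSE
  # optimize never returns the exact endpoints; check them explicitly
  for (bnd in c(-0.999, 0.999)) {
    if (abs(rho - bnd) < 2e-3 && ll(bnd) >= opt$objective) {
      rho <- bnd
      boundary <- TRUE
    }
  }
  if (boundary)
    warning("polychoric estimate at the correlation boundary")
  se <- NA_real_
  if (seTheta && !boundary) {
    h <- 1e-4
    info <- -(ll(rho + h) - 2 * ll(rho) + ll(rho - h)) / h^2
    if (is.finite(info) && info > 0) se <- sqrt(1 / info)
  }
  list(rho = rho, se = se, boundary = boundary, loglik = ll(rho), n = n)
}

# per-observation score d/d rho of the polyserial log-likelihood; z is the
# standardized covariate, ki the 1-based category index, taue = c(-Inf, tau, Inf)
.polyserialScore <- function(rho, taue, z, ki) {
  s <- sqrt(1 - rho^2)
  up <- (taue[ki + 1L] - rho * z) / s
  lo <- (taue[ki] - rho * z) / s
  P <- pmax(pnorm(up) - pnorm(lo), 1e-12)
  # derivative of (tau - rho z)/s wrt rho is (-z s + (tau - rho z) rho / s)/s^2
  dArgUp <- (-z * s + (taue[ki + 1L] - rho * z) * rho / s) / s^2
  dArgLo <- (-z * s + (taue[ki] - rho * z) * rho / s) / s^2
  dP <- ifelse(is.finite(up), dnorm(up) * dArgUp, 0) -
    ifelse(is.finite(lo), dnorm(lo) * dArgLo, 0)
  dP / P
}

#' Two-step polyserial correlation
#'
#' Maximum likelihood estimate of the correlation between the normal
#' variable underlying an ordinal item and an observed numeric covariate,
#' with the item thresholds fixed at their margin estimates and the
#' covariate standardized internally.
#'
#' @param x integer item responses (categories 0..K-1).
#' @param v numeric covariate; must have nonzero variance.
#' @param tau optional fixed thresholds as returned by
#'   \code{\link{estimateThresholds}} (estimated from \code{x} if missing).
#' @return list with elements \code{rho}, \code{se}, \code{n}.
#' @export
polyserialCorrelation <- function(x, v, tau = NULL) {
  keep <- !is.na(x) & !is.na(v)
  x <- x[keep]; v <- v[keep]
  if (stats::sd(v) == 0) stop("covariate is constant")
  if (is.null(tau))
    tau <- estimateThresholds(tabulate(x + 1L, nbins = max(x) + 1L))
  map <- attr(tau, "map")
  ki <- if (is.null(map)) x + 1L else map[x + 1L]
  z <- (v - mean(v)) / stats::sd(v)
  taue <- c(-Inf, as.numeric(tau), Inf)
  nll <- function(rho) {
    s <- sqrt(1 - rho^2)
    P <- pnorm((taue[ki + 1L] - rho * z) / s) - pnorm((taue[ki] - rho * z) / s)
    -sum(log(pmax(P, 1e-12)))
  }
  opt <- stats::optimize(nll, c(-0.995, 0.995), tol = 1e-7)
  rho <- opt$minimum
  h <- 1e-4
  info <- (nll(rho + h) - 2 * nll(rho) + nll(rho - h)) / h^2
  se <- if (is.finite(info) && info > 0) sqrt(1 / info) else NA_real_
  list(rho = rho, se = se, n = length(x))
}

#' Bivariate normality diagnostic for one pair of ordinal items
#'
#' Pearson chi-square of the observed cell counts against the counts implied
#' by the fitted bivariate normal (thresholds fixed, correlation as fitted),
#' summarized as an RMSEA with \code{df = RC - 1 - 1} (the single fitted
#' parameter is the correlation).  Pairs with RMSEA above 0.1 fail the
#' underlying-normality screen.
#'
#' @param tab R x C contingency table.
#' @param rho fitted polychoric correlation.
#' @param tauRow,tauCol fixed thresholds.
#' @return list with \code{rmsea}, \code{chisq}, \code{df}, \code{flag}.
#' @export
bivariateNormalityRmsea <- function(tab, rho, tauRow, tauCol) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  expd <- n * .cellProbs(rho, tauRow, tauCol)
  chisq <- sum((tab - expd)^2 / expd)
  df <- nrow(tab) * ncol(tab) - 1L - 1L
  rmsea <- sqrt(max(0, (chisq - df) / (df * n)))
  list(rmsea = rmsea, chisq = chisq, df = df, flag = rmsea > 0.1)
}
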