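#' @include semcore-models.R
NULL

# solve with a small ridge fallback for near-singular weight matrices
.solveRidge <- function(A, b, label = "matrix") {
  out <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(out)) {
    warning(label, " is numerically singular; ridge-regularized inverse used")
    out <- solve(A + diag(1e-8 * mean(diag(A)), nrow(A)), b)
  }
  out
}

#' RMSEA with 90 percent confidence interval
#'
#' \eqn{RMSEA = \sqrt{G \, \max(0, \chi^2 - df) / (df \, N)}} with G the
#' number of groups and N the total sample size.  The interval inverts the
#' noncentral chi-square distribution in the noncentrality parameter (lower
#' bound from the 0.95 quantile condition, upper from 0.05), transformed by
#' the same formula.  Values below .05 are conventionally read as close and
#' below .08 as reasonable approximate fit.
#'
#' @param chisq chi-square statistic.
#' @param df model degrees of freedom (> 0).
#' @param nTotal total sample size across groups.
#' @param nGroups number of groups.
#' @return list with \code{rmsea}, \code{lo90}, \code{hi90}.
#' @export
rmseaWithCi <- function(chisq, df, nTotal, nGroups = 1L) {
  if (df <= 0) stop("RMSEA is undefined for df = 0")
  if (nTotal <= 1) stop("nTotal must exceed 1")
  toR <- function(ncp) sqrt(nGroups * ncp / (df * nTotal))
  rmsea <- toR(max(0, chisq - df))
  ncpSolve <- function(q) {
    # largest ncp with pchisq(chisq, df, ncp) >= q; 0 if already below at 0
    if (pchisq(chisq, df) < q) return(0)
    hi <- max(chisq * 2, df + 100)
    while (pchisq(chisq, df, ncp = hi) > q) hi <- hi * 2
    stats::uniroot(function(l) pchisq(chisq, df, ncp = l) - q,
                   c(0, hi), tol = 1e-8)$root
  }
  list(rmsea = rmsea, lo90 = toR(ncpSolve(0.95)), hi90 = toR(ncpSolve(0.05)))
}

#' Chi-square difference test for nested models
#'
#' Difference in WLS chi-square between a more constrained (nested) and a
#' less constrained (parent) model fitted to the same data, referred to a
#' central chi-square with the df difference.  A negative difference (which
#' can occur with DWLS point estimates) is returned with a warning flag and
#' p = 1.
#'
#' @param nested,parent \linkS4class{FitResult}s, or lists with elements
#'   \code{chisq} and \code{df}.
#' @param alpha significance gate reported in \code{significant}
#'   (default .001).
#' @return list with \code{diff}, \code{dfDiff}, \code{p},
#'   \code{significant}, \code{nonMonotone}.
#' @export
chisqDiffTest <- function(nested, parent, alpha = 0.001) {
  gx <- function(x, what) if (is(x, "FitResult")) slot(x, what) else x[[what]]
  diff <- gx(nested, "chisq") - gx(parent, "chisq")
  dfDiff <- gx(nested, "df") - gx(parent, "df")
  if (dfDiff <= 0) stop("nested model must have larger df than parent")
  nonMonotone <- diff < 0
  p <- if (nonMonotone) 1 else pchisq(diff, dfDiff, lower.tail = FALSE)
  list(diff = diff, dfDiff = as.integer(dfDiff), p = p,
       significant = p < alpha, nonMonotone = nonMonotone)
}

#' Scaled DWLS discrepancy difference test
#'
#' Satorra-Bentler-type difference test on the DWLS discrepancies of two
#' nested fits: \eqn{\Delta T = (N-1)(F_0 - F_1)} scaled by
#' \eqn{\bar c = tr[(U_0 - U_1)\Gamma] / \Delta df}, where \eqn{U_i} is the
#' DWLS residual operator of model i and \eqn{\Gamma} the full moment
#' asymptotic covariance, referred to a central chi-square with
#' \eqn{\Delta df}.  For a single released parameter the scaled statistic is
#' exactly asymptotically chi-square(1); unlike differencing two full-weight
#' statistics it needs no inversion of \eqn{\Gamma}, which keeps the .001
#' gate calibrated in the iterative searches.
#'
#' @param nested,parent \linkS4class{FitResult}s of the more and less
#'   constrained model fitted to the same data.
#' @param alpha significance gate (default .001).
#' @return list with \code{diff} (scaled statistic), \code{dfDiff},
#'   \code{p}, \code{significant}, \code{nonMonotone}, \code{scaling}.
#' @export
scaledChisqDiffTest <- function(nested, parent, alpha = 0.001) {
  dfDiff <- nested@df - parent@df
  if (dfDiff <= 0) stop("nested model must have larger df than parent")
  rawDiff <- (nested@nTotal - 1) * (nested@discrepancy - parent@discrepancy)
  cbar <- (nested@traceUG - parent@traceUG) / dfDiff
  nonMonotone <- rawDiff < 0 || cbar <= 0
  scaled <- if (nonMonotone) 0 else rawDiff / cbar
  p <- if (nonMonotone) 1 else pchisq(scaled, dfDiff, lower.tail = FALSE)
  list(diff = scaled, dfDiff = as.integer(dfDiff), p = p,
       significant = p < alpha, nonMonotone = nonMonotone,
       scaling = cbar)
}

#' Full-weight WLS chi-square of a fitted model
#'
#' Residual-based WLS test statistic: with moment residuals
#' \eqn{r = s - \sigma(\hat\theta)} at the DWLS estimates, model Jacobian
#' \eqn{J} and full moment asymptotic covariance \eqn{\Gamma},
#' \deqn{T = (N-1)\, r' [\Gamma^{-1} - \Gamma^{-1} J (J'\Gamma^{-1}J)^{-1}
#'       J'\Gamma^{-1}] r.}
#' Projecting out the model tangent space in the \eqn{\Gamma} metric makes
#' T asymptotically central chi-square with the model df when the model
#' holds, for any consistent estimator — in particular the DWLS estimator,
#' whose own minimized discrepancy has no chi-square reference distribution.
#'
#' @param fit a \linkS4class{FitResult}.
#' @param stage1 the \linkS4class{Stage1Result} the model was fitted to.
#' @return list with \code{chisq}, \code{df}, \code{p}.
#' @export
wlsChisq <- function(fit, stage1) {
  r <- fit@residuals
  G <- stage1@acov[names(r), names(r)]
  Gr <- .solveRidge(G, r, "acov")
  chisq <- drop(crossprod(r, Gr))
  J <- fit@jacobian
  if (nrow(J) == length(r) && ncol(J)) {
    GJ <- .solveRidge(G, J, "acov")
    JGr <- crossprod(J, Gr)
    chisq <- chisq - drop(crossprod(JGr, .solveRidge(crossprod(J, GJ), JGr,
                                                     "projected information")))
  }
  chisq <- max(0, (fit@nTotal - 1) * chisq)
  list(chisq = chisq, df = fit@df,
       p = pchisq(chisq, fit@df, lower.tail = FALSE))
}

#' Fit a factor model to Stage 1 moments by DWLS
#'
#' Minimizes \eqn{(s - \sigma(\theta))' W_d^{-1} (s - \sigma(\theta))} with
#' \eqn{W_d} the diagonal of the moment asymptotic covariance, by
#' Levenberg-Marquardt least squares.  Model fit is then summarized by the
#' full-weight WLS chi-square at the DWLS estimates, its p value, and the
#' RMSEA with 90 percent interval; parameter uncertainty by robust
#' (sandwich) standard errors using the full asymptotic covariance.
#'
#' @param model a \linkS4class{ModelSpec}.
#' @param stage1 a \linkS4class{Stage1Result} covering the model's
#'   variables.
#' @param start optional named starting values for the free parameters
#'   (warm starts during the iterative search).
#' @return a \linkS4class{FitResult}.
#' @export
fitDwls <- function(model, stage1, start = NULL) {
  prob <- .fitProblem(model, stage1)
  s <- stage1@moments[prob$momNames]
  w <- 1 / pmax(diag(stage1@acov)[prob$momNames], 1e-10)
  sw <- sqrt(w)
  df <- countDf(model)
  # identification identities cancel in pairs, so fitted df must equal the
  # declared bookkeeping
  stopifnot(length(s) - length(prob$start) == df)

  par0 <- prob$start
  if (!is.null(start)) {
    idx <- match(names(start), prob$parNames)
    par0[idx[!is.na(idx)]] <- start[!is.na(idx)]
  }
  residFn <- function(par) sw * (s - prob$implied(par))
  jacFn <- function(par) -sw * prob$jac(par)
  ctl <- minpack.lm::nls.lm.control(maxiter = 500L, ftol = 1e-12,
                                    ptol = 1e-12, factor = 10)
  lm <- minpack.lm::nls.lm(par = par0, fn = residFn, jac = jacFn,
                           control = ctl)
  est <- lm$par
  names(est) <- prob$parNames
  converged <- lm$info %in% 1:4
  resid <- s - prob$implied(est)
  discrepancy <- sum(w * resid^2)

  nTotal <- sum(stage1@nPerGroup)
  nGroups <- model@nGroups
  J <- prob$jac(est)
  A <- crossprod(J, w * J)
  Gm <- stage1@acov[prob$momNames, prob$momNames]
  JW <- w * J
  B <- crossprod(JW, Gm %*% JW)
  Ainv <- .solveRidge(A, diag(nrow(A)), "information")
  Vp <- Ainv %*% B %*% Ainv / nTotal
  ses <- sqrt(pmax(diag(Vp), 0))
  names(ses) <- prob$parNames
  # tr(U Gamma) with U the DWLS residual operator: the scaling constant of
  # the asymptotic distribution of the minimized discrepancy
  trUG <- sum(w * diag(Gm)) - sum(diag(Ainv %*% B))

  fit <- new("FitResult", model = model,
             estimates = c(est, prob$derived(est)),
             robustSes = ses, discrepancy = discrepancy,
             chisq = 0, df = df, pValue = 1,
             rmsea = 0, rmseaCi = c(0, 0), converged = converged,
             nTotal = as.integer(nTotal), nGroups = as.integer(nGroups),
             residuals = resid,
             implied = stats::setNames(prob$implied(est), prob$momNames),
             jacobian = J, traceUG = trUG)
  wc <- wlsChisq(fit, stage1)
  fit@chisq <- wc$chisq
  fit@pValue <- wc$p
  if (df > 0L) {
    rm <- rmseaWithCi(wc$chisq, df, nTotal, nGroups)
    fit@rmsea <- rm$rmsea
    fit@rmseaCi <- c(rm$lo90, rm$hi90)
  }
  fit
}
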