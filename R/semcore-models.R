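#' @include AllClasses.R AllGenerics.R
NULL

#' Multigroup one-factor model specification
#'
#' @param nItems number of items.
#' @param variant "measurement" (no across-group constraints; factor mean 0
#'   and variance 1 in both groups) or "constrained" (loadings and intercepts
#'   equal across groups, focal factor mean/variance free — the No-Item-Bias
#'   pattern, possibly with per-item exemptions from the search).
#' @param freeNu,freeLambda item indices whose intercept/loading equality
#'   constraint is released ("constrained" variant).
#' @param thetaEqual also constrain residual variances equal across groups
#'   (never offered as bias candidates; default FALSE, which reproduces the
#'   standard df arithmetic).
#' @param itemNames labels.
#' @return a \linkS4class{ModelSpec}.
#' @export
mgModel <- function(nItems, variant = c("constrained", "measurement"),
                    freeNu = integer(0), freeLambda = integer(0),
                    thetaEqual = FALSE,
                    itemNames = paste0("item", seq_len(nItems))) {
  variant <- match.arg(variant)
  new("ModelSpec", family = "mg", variant = variant,
      nItems = as.integer(nItems), nGroups = 2L,
      itemFactor = rep(1L, nItems),
      freeNu = as.integer(sort(unique(freeNu))),
      freeLambda = as.integer(sort(unique(freeLambda))),
      violatorNames = character(0),
      freeDirect = matrix(0L, 0L, 2L), thetaEqual = thetaEqual,
      itemNames = itemNames)
}

#' Multidimensional (restricted factor analysis) model specification
#'
#' Single-group model with one or two correlated common factors (variance 1,
#' mean 0), simple-structure loadings, and optionally exogenous violator
#' variables that correlate freely with the factors and each other while
#' their direct effects on items are fixed at zero unless listed in
#' \code{freeDirect}.
#'
#' @param nItems number of items.
#' @param itemFactor factor assignment per item (1 or 2).
#' @param violatorNames exogenous violators included in the model.
#' @param freeDirect two-column matrix of freed (item, violator) direct
#'   effects.
#' @param itemNames labels.
#' @return a \linkS4class{ModelSpec}.
#' @export
mdModel <- function(nItems, itemFactor = rep(1L, nItems),
                    violatorNames = character(0),
                    freeDirect = matrix(0L, 0L, 2L),
                    itemNames = paste0("item", seq_len(nItems))) {
  freeDirect <- matrix(as.integer(freeDirect), ncol = 2L)
  new("ModelSpec", family = "md", variant = "rfa",
      nItems = as.integer(nItems), nGroups = 1L,
      itemFactor = as.integer(itemFactor),
      freeNu = integer(0), freeLambda = integer(0),
      violatorNames = as.character(violatorNames),
      freeDirect = freeDirect, thetaEqual = FALSE, itemNames = itemNames)
}

#' @describeIn countDf Degrees of freedom of the declared model.  Modeled
#'   moments are, per group, the p observed means plus p(p+1)/2
#'   variances/covariances (p counts items plus any exogenous violators);
#'   free parameters are counted as equality classes: releasing one
#'   cross-group equality or one direct effect adds one class.
#' @export
setMethod("countDf", "ModelSpec", function(model) {
  p <- model@nItems
  if (model@family == "mg") {
    moments <- 2L * (p + p * (p + 1L) / 2L)
    free <- if (model@variant == "measurement") {
      6L * p  # per group: p loadings, p intercepts, p residual variances
    } else {
      # loadings and intercepts equal across groups (one class per item,
      # split in two by each exemption), residual variances free per group
      # (or one shared class per item with thetaEqual), focal factor mean
      # and variance free
      (p + length(model@freeLambda)) + (p + length(model@freeNu)) +
        (if (model@thetaEqual) p else 2L * p) + 2L
    }
  } else {
    q <- length(model@violatorNames)
    m <- length(unique(model@itemFactor))
    P <- p + q
    moments <- P + P * (P + 1L) / 2L
    free <- p + p + p +                # loadings, intercepts, residuals
      m * (m - 1L) / 2L +              # factor correlation(s)
      q * m +                          # violator-factor covariances
      q * (q - 1L) / 2L +              # violator-violator covariances
      2L * q +                         # violator means and variances
      nrow(model@freeDirect)           # released direct effects
  }
  df <- as.integer(moments - free)
  if (df < 0L) stop("over-parameterized model: negative degrees of freedom")
  df
})

# ---------------------------------------------------------------------------
# translation of a declared model into the fitted optimization problem.
# Identification identities (reference/single-group underlying means 0 and
# variances 1; standardized violators) remove matched (moment, parameter)
# pairs, so the fitted df equals the declared df — asserted in fitDwls.

.fitProblem <- function(model, stage1) {
  items <- stage1@itemNames
  p <- length(items)
  stopifnot(model@nItems == p)
  if (model@family == "mg") {
    stopifnot(stage1@design == "multigroup")
    pairIdx <- which(upper.tri(diag(p)), arr.ind = TRUE)
    pairIdx <- pairIdx[order(pairIdx[, 1L], pairIdx[, 2L]), , drop = FALSE]
    momNames <- c(paste0("mean.f:", items),
                  paste0("var.f:", items),
                  paste0("corr.r:", items[pairIdx[, 1L]], ":", items[pairIdx[, 2L]]),
                  paste0("cov.f:", items[pairIdx[, 1L]], ":", items[pairIdx[, 2L]]))
    i1 <- pairIdx[, 1L]; i2 <- pairIdx[, 2L]
    fm <- stage1@moments[paste0("mean.f:", items)]
    fv <- stage1@moments[paste0("var.f:", items)]
    if (model@variant == "measurement") {
      parNames <- c(paste0("lambda.ref.", items), paste0("lambda.foc.", items),
                    paste0("nu.foc.", items), paste0("theta.foc.", items))
      start <- c(rep(0.7, p), rep(0.7, p), fm, pmax(fv - 0.49, 0.1))
      implied <- function(par) {
        lamR <- par[1:p]; lamF <- par[p + 1:p]
        nuF <- par[2 * p + 1:p]; thF <- par[3 * p + 1:p]
        c(nuF, lamF^2 + thF, lamR[i1] * lamR[i2], lamF[i1] * lamF[i2])
      }
      derived <- function(par) {
        lamR <- par[1:p]
        c(stats::setNames(rep(0, p), paste0("nu.ref.", items)),
          stats::setNames(1 - lamR^2, paste0("theta.ref.", items)),
          kappa.ref = 0, phi.ref = 1, kappa.foc = 0, phi.foc = 1)
      }
      P2 <- nrow(pairIdx)
      jac <- function(par) {
        lamR <- par[1:p]; lamF <- par[p + 1:p]
        J <- matrix(0, 2 * p + 2 * P2, 4 * p)
        J[cbind(1:p, 2 * p + 1:p)] <- 1                    # means / nuF
        J[cbind(p + 1:p, p + 1:p)] <- 2 * lamF             # vars / lamF
        J[cbind(p + 1:p, 3 * p + 1:p)] <- 1                # vars / thF
        r0 <- 2 * p
        J[cbind(r0 + seq_len(P2), i1)] <- lamR[i2]
        J[cbind(r0 + seq_len(P2), i2)] <- lamR[i1]
        r0 <- 2 * p + P2
        J[cbind(r0 + seq_len(P2), p + i1)] <- lamF[i2]
        J[cbind(r0 + seq_len(P2), p + i2)] <- lamF[i1]
        J
      }
    } else {
      fL <- model@freeLambda; fN <- model@freeNu
      tEq <- isTRUE(model@thetaEqual)
      # with equal residual variances the shared theta is pinned by the
      # reference-group unit-variance identity: theta_i = 1 - lambda_i^2
      parNames <- c(paste0("lambda.", items),
                    if (length(fL)) paste0("lambda.foc.", items[fL]),
                    if (length(fN)) paste0("nu.foc.", items[fN]),
                    if (!tEq) paste0("theta.foc.", items),
                    "kappa.foc", "phi.foc")
      start <- c(rep(0.7, p), rep(0.7, length(fL)),
                 fm[fN], if (!tEq) pmax(fv - 0.49, 0.1), 0, 1)
      nL <- length(fL); nN <- length(fN)
      nT <- if (tEq) 0L else p
      implied <- function(par) {
        lam <- par[1:p]
        lamF <- lam
        if (nL) lamF[fL] <- par[p + seq_len(nL)]
        nu <- rep(0, p)
        if (nN) nu[fN] <- par[p + nL + seq_len(nN)]
        thF <- if (tEq) 1 - lam^2 else par[p + nL + nN + 1:p]
        kap <- par[p + nL + nN + nT + 1L]
        phi <- par[p + nL + nN + nT + 2L]
        c(nu + lamF * kap, lamF^2 * phi + thF,
          lam[i1] * lam[i2], lamF[i1] * lamF[i2] * phi)
      }
      derived <- function(par) {
        lam <- par[1:p]
        c(stats::setNames(rep(0, p), paste0("nu.ref.", items)),
          stats::setNames(1 - lam^2, paste0("theta.ref.", items)),
          if (tEq) stats::setNames(1 - lam^2, paste0("theta.foc.", items)),
          kappa.ref = 0, phi.ref = 1)
      }
      P2 <- nrow(pairIdx)
      npar <- p + nL + nN + nT + 2L
      # column of the parameter feeding the focal loading of item i
      srcCol <- seq_len(p)
      if (nL) srcCol[fL] <- p + seq_len(nL)
      jac <- function(par) {
        lam <- par[1:p]
        lamF <- lam
        if (nL) lamF[fL] <- par[p + seq_len(nL)]
        kap <- par[p + nL + nN + nT + 1L]
        phi <- par[p + nL + nN + nT + 2L]
        J <- matrix(0, 2 * p + 2 * P2, npar)
        kapCol <- p + nL + nN + nT + 1L
        phiCol <- kapCol + 1L
        J[cbind(1:p, srcCol)] <- kap                       # means / loading
        if (nN) J[cbind(fN, p + nL + seq_len(nN))] <- 1    # means / nuF
        J[, kapCol][1:p] <- lamF
        J[cbind(p + 1:p, srcCol)] <- 2 * lamF * phi        # vars
        if (tEq) {
          # vars also move through the pinned theta = 1 - lambda^2
          J[cbind(p + 1:p, 1:p)] <- J[cbind(p + 1:p, 1:p)] - 2 * lam
        } else {
          J[cbind(p + 1:p, p + nL + nN + 1:p)] <- 1
        }
        J[, phiCol][p + 1:p] <- lamF^2
        r0 <- 2 * p
        J[cbind(r0 + seq_len(P2), i1)] <- lam[i2]          # reference corrs
        J[cbind(r0 + seq_len(P2), i2)] <- lam[i1]
        r0 <- 2 * p + P2
        J[cbind(r0 + seq_len(P2), srcCol[i1])] <- lamF[i2] * phi
        J[cbind(r0 + seq_len(P2), srcCol[i2])] <- lamF[i1] * phi
        J[, phiCol][r0 + seq_len(P2)] <- lamF[i1] * lamF[i2]
        J
      }
    }
  } else {
    q <- length(model@violatorNames)
    if (q) stopifnot(all(model@violatorNames %in% stage1@covariateNames))
    m <- max(model@itemFactor)
    pairIdx <- which(upper.tri(diag(p)), arr.ind = TRUE)
    pairIdx <- pairIdx[order(pairIdx[, 1L], pairIdx[, 2L]), , drop = FALSE]
    momNames <- paste0("corr:", items[pairIdx[, 1L]], ":", items[pairIdx[, 2L]])
    if (q) {
      iv <- expand.grid(cc = seq_len(q), i = seq_len(p))[, 2:1]
      momNames <- c(momNames,
                    paste0("cov.iv:", items[iv$i], ":", model@violatorNames[iv$cc]))
      if (q > 1L) {
        vp <- which(upper.tri(diag(q)), arr.ind = TRUE)
        vp <- vp[order(vp[, 1L], vp[, 2L]), , drop = FALSE]
        momNames <- c(momNames, paste0("cov.vv:", model@violatorNames[vp[, 1L]],
                                       ":", model@violatorNames[vp[, 2L]]))
      }
    }
    nPsi <- m * (m - 1L) / 2L
    nFV <- m * q
    nVV <- q * (q - 1L) / 2L
    nB <- nrow(model@freeDirect)
    parNames <- c(paste0("lambda.", items),
                  if (nPsi) "psi.f1.f2",
                  if (nFV) paste0("cov.", rep(paste0("f", seq_len(m)), q), ".",
                                  rep(model@violatorNames, each = m)),
                  if (nVV) {
                    vp2 <- which(upper.tri(diag(q)), arr.ind = TRUE)
                    paste0("cov.", model@violatorNames[vp2[, 1L]], ".",
                           model@violatorNames[vp2[, 2L]])
                  },
                  if (nB) paste0("beta.", items[model@freeDirect[, 1L]], ".",
                                 model@violatorNames[model@freeDirect[, 2L]]))
    start <- c(rep(0.7, p), rep(0.5, nPsi), rep(0, nFV), rep(0, nVV),
               rep(0, nB))
    iF <- model@itemFactor
    fd <- model@freeDirect
    implied <- function(par) {
      lam <- par[1:p]
      L <- matrix(0, p + q, m + q)
      L[cbind(seq_len(p), iF)] <- lam
      if (q) L[cbind(p + seq_len(q), m + seq_len(q))] <- 1
      idx <- p
      Psi <- diag(m + q)
      if (nPsi) { Psi[1L, 2L] <- Psi[2L, 1L] <- par[idx + 1L]; idx <- idx + 1L }
      if (nFV) {
        cfv <- matrix(par[idx + seq_len(nFV)], m, q)
        Psi[seq_len(m), m + seq_len(q)] <- cfv
        Psi[m + seq_len(q), seq_len(m)] <- t(cfv)
        idx <- idx + nFV
      }
      if (nVV) {
        vp2 <- which(upper.tri(diag(q)), arr.ind = TRUE)
        for (r in seq_len(nVV)) {
          Psi[m + vp2[r, 1L], m + vp2[r, 2L]] <-
            Psi[m + vp2[r, 2L], m + vp2[r, 1L]] <- par[idx + r]
        }
        idx <- idx + nVV
      }
      if (nB) for (r in seq_len(nB))
        L[fd[r, 1L], m + fd[r, 2L]] <- par[idx + r]
      S <- L %*% Psi %*% t(L)
      out <- S[cbind(pairIdx[, 1L], pairIdx[, 2L])]
      if (q) {
        ivm <- as.matrix(expand.grid(cc = p + seq_len(q), i = seq_len(p)))[, 2:1]
        out <- c(out, S[ivm])
        if (q > 1L) {
          vp2 <- which(upper.tri(diag(q)), arr.ind = TRUE)
          out <- c(out, S[cbind(p + vp2[, 1L], p + vp2[, 2L])])
        }
      }
      out
    }
    derived <- function(par) {
      # residual variances absorb the unit-variance identity of the
      # standardized underlying items
      full <- implied(par)
      lam <- par[1:p]
      L <- matrix(0, p + q, m + q)
      L[cbind(seq_len(p), iF)] <- lam
      if (q) L[cbind(p + seq_len(q), m + seq_len(q))] <- 1
      if (nB) for (r in seq_len(nB))
        L[fd[r, 1L], m + fd[r, 2L]] <- par[p + nPsi + nFV + nVV + r]
      Psi <- diag(m + q)
      if (nPsi) Psi[1L, 2L] <- Psi[2L, 1L] <- par[p + 1L]
      if (nFV) {
        cfv <- matrix(par[p + nPsi + seq_len(nFV)], m, q)
        Psi[seq_len(m), m + seq_len(q)] <- cfv
        Psi[m + seq_len(q), seq_len(m)] <- t(cfv)
      }
      if (nVV) {
        vp2 <- which(upper.tri(diag(q)), arr.ind = TRUE)
        for (r in seq_len(nVV))
          Psi[m + vp2[r, 1L], m + vp2[r, 2L]] <-
            Psi[m + vp2[r, 2L], m + vp2[r, 1L]] <- par[p + nPsi + nFV + r]
      }
      commonVar <- diag(L %*% Psi %*% t(L))[seq_len(p)]
      c(stats::setNames(1 - commonVar, paste0("theta.", items)),
        stats::setNames(rep(0, p), paste0("nu.", items)))
    }
    # moment rows as (A, B) entries of the joint covariance matrix
    A <- pairIdx[, 1L]; B <- pairIdx[, 2L]
    if (q) {
      iv <- expand.grid(cc = seq_len(q), i = seq_len(p))[, 2:1]
      A <- c(A, iv$i); B <- c(B, p + iv$cc)
      if (q > 1L) {
        vp2 <- which(upper.tri(diag(q)), arr.ind = TRUE)
        vp2 <- vp2[order(vp2[, 1L], vp2[, 2L]), , drop = FALSE]
        A <- c(A, p + vp2[, 1L]); B <- c(B, p + vp2[, 2L])
      }
    }
    npar <- p + nPsi + nFV + nVV + nB
    jac <- function(par) {
      lam <- par[1:p]
      L <- matrix(0, p + q, m + q)
      L[cbind(seq_len(p), iF)] <- lam
      if (q) L[cbind(p + seq_len(q), m + seq_len(q))] <- 1
      Psi <- diag(m + q)
      if (nPsi) Psi[1L, 2L] <- Psi[2L, 1L] <- par[p + 1L]
      if (nFV) {
        cfv <- matrix(par[p + nPsi + seq_len(nFV)], m, q)
        Psi[seq_len(m), m + seq_len(q)] <- cfv
        Psi[m + seq_len(q), seq_len(m)] <- t(cfv)
      }
      if (nVV) {
        vp2 <- which(upper.tri(diag(q)), arr.ind = TRUE)
        for (r in seq_len(nVV))
          Psi[m + vp2[r, 1L], m + vp2[r, 2L]] <-
            Psi[m + vp2[r, 2L], m + vp2[r, 1L]] <- par[p + nPsi + nFV + r]
      }
      if (nB) for (r in seq_len(nB))
        L[fd[r, 1L], m + fd[r, 2L]] <- par[p + nPsi + nFV + nVV + r]
      M1 <- Psi %*% t(L)
      M2 <- L %*% Psi
      J <- matrix(0, length(A), npar)
      dL <- function(i, j0) (A == i) * M1[j0, B] + (B == i) * M2[cbind(A, j0)]
      dPsi <- function(r, c) L[cbind(A, r)] * L[cbind(B, c)] +
        L[cbind(A, c)] * L[cbind(B, r)]
      for (i in seq_len(p)) J[, i] <- dL(i, iF[i])
      col <- p
      if (nPsi) { J[, col + 1L] <- dPsi(1L, 2L); col <- col + 1L }
      if (nFV) {
        for (k in seq_len(q)) for (f in seq_len(m)) {
          col <- col + 1L
          J[, col] <- dPsi(f, m + k)
        }
      }
      if (nVV) {
        vp2 <- which(upper.tri(diag(q)), arr.ind = TRUE)
        for (r in seq_len(nVV)) {
          col <- col + 1L
          J[, col] <- dPsi(m + vp2[r, 1L], m + vp2[r, 2L])
        }
      }
      if (nB) for (r in seq_len(nB)) {
        col <- col + 1L
        J[, col] <- dL(fd[r, 1L], m + fd[r, 2L])
      }
      J
    }
  }
  stopifnot(all(momNames %in% names(stage1@moments)))
  list(momNames = momNames, parNames = parNames, start = start,
       implied = implied, jac = jac, derived = derived)
}
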