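#' @include polychoric.R AllClasses.R
NULL

# Stage 1 turns an ordinal dataset into the stacked moment vector the factor
# models are fitted to, together with its asymptotic covariance.  Every
# estimate is a smooth function of sample proportions/moments, so the
# asymptotic covariance is assembled from per-observation influence
# contributions: acov = (1/N) sum_z IF_z IF_z', with chains through the
# pooled thresholds, the focal-group margin fit, and the pairwise scores.

# Ledoit-Wolf-style shrinkage of the moment asymptotic covariance toward its
# diagonal.  With q moments estimated from N influence rows the sample
# covariance's small eigenvalues are biased low and its inverse overweights
# them, fattening the tails of the full-weight chi-square; shrinking the
# off-diagonal by the estimated noise-to-signal ratio restores calibration
# while leaving the DWLS weights (the diagonal) untouched.
.shrinkAcov <- function(G, IF) {
  N <- nrow(IF)
  S2 <- crossprod(IF^2) / N          # E[w_i^2 w_j^2]
  V <- (S2 - G^2) / N                # approx var of each covariance entry
  off <- !diag(nrow(G))
  num <- sum(V[off])
  den <- sum(G[off]^2)
  w <- if (den > 0) min(1, max(0, num / den)) else 0
  Gs <- (1 - w) * G
  diag(Gs) <- diag(G)
  attr(Gs, "shrinkage") <- w
  Gs
}

# numeric Jacobian of a vector-valued function at x (central differences)
.numJac <- function(f, x, h = 1e-5) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# gradient of the least-squares criterion for the focal underlying moments
.umGrad <- function(mu, sig, tau, Q) {
  u <- (tau - mu) / sig
  r <- pnorm(u) - Q
  d <- dnorm(u)
  c(sum(r * (-d / sig)), sum(r * (-d * u / sig)))
}

# influence rows (2 x N) of the focal underlying mean/SD given influence
# rows of the thresholds and of the focal cumulative proportions
.umInfluence <- function(mu, sig, tau, Q, IFtau, IFQ) {
  if (length(tau) < 2L) {
    IFmu <- IFtau[, 1L] - IFQ[, 1L] / dnorm(qnorm(Q[1L]))
    return(rbind(mu = IFmu, sigma = 0))
  }
  H <- .numJac(function(x) .umGrad(x[1L], x[2L], tau, Q), c(mu, sig))
  A <- .numJac(function(tt) .umGrad(mu, sig, tt, Q), tau)
  B <- .numJac(function(qq) .umGrad(mu, sig, tau, qq), Q)
  M <- A %*% t(IFtau) + B %*% t(IFQ)
  out <- -solve(H, M)
  rownames(out) <- c("mu", "sigma")
  out
}

# polychoric influence rows for one pair in one group.
# aIF / bIF: N x (K-1) influence matrices of the effective thresholds;
# inGroup: logical N; propShare: group proportion of the total sample
.polychoricInfluence <- function(rho, a, b, tab, ki, kj, inGroup, propShare,
                                 aIF, bIF) {
  props <- tab / sum(tab)
  Sfun <- function(rho, a, b) .polychoricScore(rho, a, b, props)
  h <- 1e-4
  dSdrho <- (Sfun(rho + h, a, b) - Sfun(rho - h, a, b)) / (2 * h)
  if (!is.finite(dSdrho) || abs(dSdrho) < 1e-12) return(numeric(length(inGroup)))
  W <- .cellProbsDrho(rho, a, b) / .cellProbs(rho, a, b)  # dS/dp cellwise
  cellPart <- numeric(length(inGroup))
  cellPart[inGroup] <- (W[cbind(ki[inGroup], kj[inGroup])] - sum(W * props)) /
    propShare
  acc <- cellPart
  for (k in seq_along(a)) {
    ap <- a; ap[k] <- a[k] + h
    am <- a; am[k] <- a[k] - h
    acc <- acc + ((Sfun(rho, ap, b) - Sfun(rho, am, b)) / (2 * h)) * aIF[, k]
  }
  for (k in seq_along(b)) {
    bp <- b; bp[k] <- b[k] + h
    bm <- b; bm[k] <- b[k] - h
    acc <- acc + ((Sfun(rho, a, bp) - Sfun(rho, a, bm)) / (2 * h)) * bIF[, k]
  }
  -acc / dSdrho
}

# core of Stage 1: moments (and optionally influence rows) from clean data.
# resp0: integer matrix of 0-based categories; groupIdx: NULL or 1/2 vector
# (1 = reference); covs: numeric matrix (0 columns allowed)
.stage1Core <- function(resp0, groupIdx, covs, computeIF = TRUE) {
  N <- nrow(resp0)
  p <- ncol(resp0)
  items <- colnames(resp0)
  multigroup <- !is.null(groupIdx)
  nc <- ncol(covs)

  tau <- vector("list", p)
  ki <- matrix(0L, N, p)
  K <- integer(p)
  IFtau <- if (computeIF) vector("list", p)
  for (i in seq_len(p)) {
    counts <- tabulate(resp0[, i] + 1L, nbins = max(resp0[, i]) + 1L)
    tt <- estimateThresholds(counts, item = items[i])
    tau[[i]] <- as.numeric(tt)
    map <- attr(tt, "map")
    ki[, i] <- map[resp0[, i] + 1L]
    K[i] <- length(tau[[i]]) + 1L
    if (computeIF) {
      P <- cumsum(attr(tt, "counts"))[-K[i]] / N
      IFtau[[i]] <- sapply(seq_len(K[i] - 1L), function(k)
        ((ki[, i] <= k) - P[k]) / dnorm(tau[[i]][k]))
      IFtau[[i]] <- matrix(IFtau[[i]], nrow = N)
    }
  }

  momNames <- character(0)
  moments <- numeric(0)
  IF <- if (computeIF) matrix(0, N, 0)
  addMoment <- function(name, value, ifrow) {
    momNames <<- c(momNames, name)
    moments <<- c(moments, value)
    if (computeIF) IF <<- cbind(IF, ifrow)
    invisible(NULL)
  }

  pairRmsea <- matrix(0, p, p, dimnames = list(items, items))
  corrs <- list()
  boundaryPairs <- character(0)

  if (multigroup) {
    # pooled thresholds describe the two-group mixture, so each group's
    # underlying location/scale is solved from its own margins against the
    # shared thresholds, and the whole solution is then rescaled so that the
    # reference group is standardized (mean 0, SD 1) — the identification
    # convention all reported moments are expressed in
    foc <- groupIdx == 2L
    muG <- sigG <- matrix(0, 2L, p)
    IFmuG <- IFsigG <- if (computeIF) array(0, c(N, 2L, p))
    for (g in 1:2) {
      inG <- if (g == 1L) !foc else foc
      share <- mean(inG)
      for (i in seq_len(p)) {
        Q <- vapply(seq_len(K[i] - 1L), function(k) mean(ki[inG, i] <= k), 0)
        ms <- .fitUnderlyingMoments(tau[[i]], Q)
        muG[g, i] <- ms["mu"]; sigG[g, i] <- ms["sigma"]
        if (computeIF) {
          IFQ <- sapply(seq_len(K[i] - 1L), function(k)
            inG * ((ki[, i] <= k) - Q[k]) / share)
          um <- .umInfluence(ms["mu"], ms["sigma"], tau[[i]], Q,
                             IFtau[[i]], matrix(IFQ, nrow = N))
          IFmuG[, g, i] <- um["mu", ]; IFsigG[, g, i] <- um["sigma", ]
        }
      }
    }
    # focal moments on the reference-standardized scale
    mus <- (muG[2L, ] - muG[1L, ]) / sigG[1L, ]
    sigs <- sigG[2L, ] / sigG[1L, ]
    IFmu <- IFsig <- if (computeIF) matrix(0, N, p)
    if (computeIF) for (i in seq_len(p)) {
      IFmu[, i] <- (IFmuG[, 2L, i] - IFmuG[, 1L, i]) / sigG[1L, i] -
        (muG[2L, i] - muG[1L, i]) / sigG[1L, i]^2 * IFsigG[, 1L, i]
      IFsig[, i] <- IFsigG[, 2L, i] / sigG[1L, i] -
        sigG[2L, i] / sigG[1L, i]^2 * IFsigG[, 1L, i]
    }
    for (i in seq_len(p))
      addMoment(paste0("mean.f:", items[i]), mus[i],
                if (computeIF) IFmu[, i])
    for (i in seq_len(p))
      addMoment(paste0("var.f:", items[i]), sigs[i]^2,
                if (computeIF) 2 * sigs[i] * IFsig[, i])

    # group-specific effective thresholds (raw scale) and their influence
    effTau <- function(g, i) (tau[[i]] - muG[g, i]) / sigG[g, i]
    effIF <- function(g, i) {
      if (!computeIF) return(NULL)
      sweep(IFtau[[i]] - IFmuG[, g, i], 2, rep(sigG[g, i], K[i] - 1L), "/") -
        outer(IFsigG[, g, i], (tau[[i]] - muG[g, i]) / sigG[g, i]^2)
    }

    rhos <- array(NA_real_, c(2L, p, p))
    IFrho <- if (computeIF) vector("list", 2L)
    if (computeIF) for (g in 1:2) IFrho[[g]] <- array(0, c(N, p, p))
    for (g in 1:2) {
      inG <- if (g == 1L) !foc else foc
      share <- mean(inG)
      for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
        tab <- table(factor(ki[inG, i], levels = seq_len(K[i])),
                     factor(ki[inG, j], levels = seq_len(K[j])))
        a <- effTau(g, i); b <- effTau(g, j)
        fit <- withCallingHandlers(
          estimatePolychoric(tab, a, b, seTheta = FALSE),
          warning = function(w) invokeRestart("muffleWarning"))
        rhos[g, i, j] <- rhos[g, j, i] <- fit$rho
        pr <- bivariateNormalityRmsea(tab, fit$rho, a, b)
        pairRmsea[i, j] <- pairRmsea[j, i] <- max(pairRmsea[i, j], pr$rmsea)
        if (fit$boundary)
          boundaryPairs <- c(boundaryPairs, paste(items[i], items[j], g))
        if (computeIF) {
          IFrho[[g]][, i, j] <- if (fit$boundary) 0 else
            .polychoricInfluence(fit$rho, a, b, tab, ki[, i], ki[, j], inG,
                                 share, effIF(g, i), effIF(g, j))
        }
      }
    }
    for (i in seq_len(p - 1L)) for (j in (i + 1L):p)
      addMoment(paste0("corr.r:", items[i], ":", items[j]), rhos[1L, i, j],
                if (computeIF) IFrho[[1L]][, i, j])
    for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
      r <- rhos[2L, i, j]
      addMoment(paste0("cov.f:", items[i], ":", items[j]),
                r * sigs[i] * sigs[j],
                if (computeIF) sigs[i] * sigs[j] * IFrho[[2L]][, i, j] +
                  r * sigs[j] * IFsig[, i] + r * sigs[i] * IFsig[, j])
    }
    for (g in 1:2) {
      R <- diag(p); R[upper.tri(R)] <- 0
      for (i in seq_len(p - 1L)) for (j in (i + 1L):p)
        R[i, j] <- R[j, i] <- rhos[g, i, j]
      dimnames(R) <- list(items, items)
      corrs[[g]] <- R
    }
    underlyingMeans <- rbind(0, mus)
    underlyingSds <- rbind(1, sigs)
    colnames(underlyingMeans) <- colnames(underlyingSds) <- items
    # report thresholds on the reference-standardized scale
    tau <- lapply(seq_len(p), function(i)
      (tau[[i]] - muG[1L, i]) / sigG[1L, i])
  } else {
    # single group: items standardized; covariates standardized and appended
    rhos <- matrix(NA_real_, p, p)
    IFrhoS <- if (computeIF) array(0, c(N, p, p))
    for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
      tab <- table(factor(ki[, i], levels = seq_len(K[i])),
                   factor(ki[, j], levels = seq_len(K[j])))
      fit <- withCallingHandlers(
        estimatePolychoric(tab, tau[[i]], tau[[j]], seTheta = FALSE),
        warning = function(w) invokeRestart("muffleWarning"))
      rhos[i, j] <- rhos[j, i] <- fit$rho
      pr <- bivariateNormalityRmsea(tab, fit$rho, tau[[i]], tau[[j]])
      pairRmsea[i, j] <- pairRmsea[j, i] <- pr$rmsea
      if (fit$boundary)
        boundaryPairs <- c(boundaryPairs, paste(items[i], items[j]))
      if (computeIF)
        IFrhoS[, i, j] <- if (fit$boundary) 0 else
          .polychoricInfluence(fit$rho, tau[[i]], tau[[j]], tab,
                               ki[, i], ki[, j], rep(TRUE, N), 1,
                               IFtau[[i]], IFtau[[j]])
    }
    for (i in seq_len(p - 1L)) for (j in (i + 1L):p)
      addMoment(paste0("corr:", items[i], ":", items[j]), rhos[i, j],
                if (computeIF) IFrhoS[, i, j])

    cnames <- colnames(covs)
    Z <- matrix(0, N, nc)
    IFz <- NULL
    psr <- matrix(NA_real_, p, nc)
    if (nc) {
      mV <- colMeans(covs)
      sdV <- apply(covs, 2, stats::sd)
      if (any(sdV == 0)) stop("constant covariate: ",
                              paste(cnames[sdV == 0], collapse = ", "))
      Z <- sweep(sweep(covs, 2, mV), 2, sdV, "/")
      # polyserial item x covariate
      for (i in seq_len(p)) for (cc in seq_len(nc)) {
        taue <- c(-Inf, tau[[i]], Inf)
        z <- Z[, cc]
        nll <- function(r) {
          s <- sqrt(1 - r^2)
          P <- pnorm((taue[ki[, i] + 1L] - r * z) / s) -
            pnorm((taue[ki[, i]] - r * z) / s)
          -sum(log(pmax(P, 1e-12)))
        }
        r <- stats::optimize(nll, c(-0.995, 0.995), tol = 1e-7)$minimum
        psr[i, cc] <- r
        ifrow <- NULL
        if (computeIF) {
          Sbar <- function(r, tt, m, s)
            mean(.polyserialScore(r, c(-Inf, tt, Inf), (covs[, cc] - m) / s, ki[, i]))
          h <- 1e-4
          dSdr <- (Sbar(r + h, tau[[i]], mV[cc], sdV[cc]) -
                     Sbar(r - h, tau[[i]], mV[cc], sdV[cc])) / (2 * h)
          acc <- .polyserialScore(r, taue, z, ki[, i])
          for (k in seq_along(tau[[i]])) {
            tp <- tau[[i]]; tp[k] <- tp[k] + h
            tm <- tau[[i]]; tm[k] <- tm[k] - h
            acc <- acc + ((Sbar(r, tp, mV[cc], sdV[cc]) -
                             Sbar(r, tm, mV[cc], sdV[cc])) / (2 * h)) *
              IFtau[[i]][, k]
          }
          dm <- (Sbar(r, tau[[i]], mV[cc] + h * sdV[cc], sdV[cc]) -
                   Sbar(r, tau[[i]], mV[cc] - h * sdV[cc], sdV[cc])) / (2 * h * sdV[cc])
          dsd <- (Sbar(r, tau[[i]], mV[cc], sdV[cc] * (1 + h)) -
                    Sbar(r, tau[[i]], mV[cc], sdV[cc] * (1 - h))) / (2 * h * sdV[cc])
          acc <- acc + dm * (covs[, cc] - mV[cc]) +
            dsd * ((covs[, cc] - mV[cc])^2 - sdV[cc]^2) / (2 * sdV[cc])
          ifrow <- -acc / dSdr
        }
        addMoment(paste0("cov.iv:", items[i], ":", cnames[cc]), r, ifrow)
      }
      if (nc > 1L) for (c1 in seq_len(nc - 1L)) for (c2 in (c1 + 1L):nc) {
        r <- stats::cor(Z[, c1], Z[, c2])
        addMoment(paste0("cov.vv:", cnames[c1], ":", cnames[c2]), r,
                  if (computeIF)
                    Z[, c1] * Z[, c2] - r * (Z[, c1]^2 + Z[, c2]^2) / 2)
      }
    }
    Rfull <- diag(p + nc)
    Rfull[seq_len(p), seq_len(p)] <- ifelse(is.na(rhos), 1, rhos)
    diag(Rfull) <- 1
    if (nc) {
      Rfull[seq_len(p), p + seq_len(nc)] <- psr
      Rfull[p + seq_len(nc), seq_len(p)] <- t(psr)
      if (nc > 1L) {
        cz <- stats::cor(Z)
        Rfull[p + seq_len(nc), p + seq_len(nc)] <- cz
      }
    }
    dimnames(Rfull) <- list(c(items, cnames), c(items, cnames))
    corrs[[1L]] <- Rfull
    underlyingMeans <- matrix(0, 1L, p, dimnames = list(NULL, items))
    underlyingSds <- matrix(1, 1L, p, dimnames = list(NULL, items))
  }

  names(moments) <- momNames
  if (computeIF) {
    IF <- sweep(IF, 2, colMeans(IF))
    colnames(IF) <- momNames
  }
  list(moments = moments, IF = if (computeIF) IF, thresholds = tau,
       correlations = corrs, underlyingMeans = underlyingMeans,
       underlyingSds = underlyingSds, pairRmsea = pairRmsea,
       boundaryPairs = boundaryPairs)
}

#' Stage 1: thresholds, correlations and asymptotic covariance
#'
#' Runs the first stage of the two-stage procedure on an ordinal dataset.
#' Thresholds are estimated from the pooled sample (imposing equality across
#' groups); in the multigroup design the reference group's underlying
#' variables are standardized and the focal group's underlying means/SDs are
#' solved from its margins relative to the shared thresholds; polychoric
#' (and, in the single-group design, polyserial and product-moment)
#' correlations are estimated pairwise; every pair is screened for bivariate
#' normality by RMSEA (flagged above 0.1); and the stacked moment vector's
#' asymptotic covariance is assembled from influence-function contributions
#' (or a stratified nonparametric bootstrap).
#'
#' @param data an \linkS4class{OrdinalDataset}.
#' @param design "multigroup" (requires a two-level group), "single_group",
#'   or "auto" (multigroup iff a group label is present).
#' @param covariateNames covariate columns to include as observed exogenous
#'   variables (single-group design; they are standardized internally).
#' @param acovMethod "influence" (default) or "bootstrap".
#' @param B,seed bootstrap replicates and seed (bootstrap method only).
#' @return a \linkS4class{Stage1Result}.  Pairs failing the normality screen
#'   are listed in \code{flaggedPairs(result)}; the procedure continues but
#'   downstream reports surface the flag.
#' @export
runStage1 <- function(data, design = c("auto", "multigroup", "single_group"),
                      covariateNames = character(0),
                      acovMethod = c("influence", "bootstrap"),
                      B = 200L, seed = 1L) {
  stopifnot(is(data, "OrdinalDataset"))
  design <- match.arg(design)
  acovMethod <- match.arg(acovMethod)
  if (design == "auto")
    design <- if (!is.null(data@group)) "multigroup" else "single_group"
  if (design == "multigroup" && is.null(data@group))
    stop("multigroup design needs a group column with two levels")

  resp <- data@responses
  covs <- if (length(covariateNames))
    as.matrix(data@covariates[, covariateNames, drop = FALSE])
  else matrix(numeric(0), nrow(resp), 0)
  keep <- stats::complete.cases(resp) &
    (if (length(covariateNames)) stats::complete.cases(covs) else TRUE) &
    (if (design == "multigroup") !is.na(data@group) else TRUE)
  nDropped <- sum(!keep)
  if (nDropped) message(nDropped, " incomplete respondent(s) dropped listwise")
  resp <- resp[keep, , drop = FALSE]
  covs <- covs[keep, , drop = FALSE]
  groupIdx <- if (design == "multigroup")
    as.integer(droplevels(data@group[keep]))
  if (design == "single_group") groupIdx <- NULL

  core <- .stage1Core(resp, groupIdx, covs, computeIF = TRUE)
  N <- nrow(resp)
  if (acovMethod == "influence") {
    acov <- .shrinkAcov(crossprod(core$IF) / N, core$IF)
  } else {
    set.seed(as.integer(seed))
    reps <- matrix(0, B, length(core$moments))
    for (b in seq_len(B)) {
      idx <- if (is.null(groupIdx)) sample.int(N, replace = TRUE) else
        unlist(lapply(1:2, function(g) {
          w <- which(groupIdx == g); sample(w, replace = TRUE)
        }))
      reps[b, ] <- .stage1Core(resp[idx, , drop = FALSE],
                               groupIdx[idx], covs[idx, , drop = FALSE],
                               computeIF = FALSE)$moments
    }
    acov <- N * stats::cov(reps)
    dimnames(acov) <- list(names(core$moments), names(core$moments))
  }

  flag <- which(core$pairRmsea > 0.1 & upper.tri(core$pairRmsea), arr.ind = TRUE)
  flagged <- cbind(rownames(core$pairRmsea)[flag[, 1L]],
                   colnames(core$pairRmsea)[flag[, 2L]])
  colnames(flagged) <- c("varA", "varB")
  if (length(core$boundaryPairs))
    warning("polychoric boundary estimate for pair(s): ",
            paste(core$boundaryPairs, collapse = "; "))

  nPerGroup <- if (is.null(groupIdx)) N else as.integer(table(groupIdx))
  new("Stage1Result",
      design = design,
      itemNames = data@itemNames,
      covariateNames = as.character(covariateNames),
      thresholds = core$thresholds,
      correlations = core$correlations,
      underlyingMeans = core$underlyingMeans,
      underlyingSds = core$underlyingSds,
      pairRmsea = core$pairRmsea,
      flaggedPairs = flagged,
      moments = core$moments,
      acov = acov,
      nPerGroup = as.integer(nPerGroup),
      groupLevels = if (design == "multigroup")
        levels(droplevels(data@group[keep])) else "all")
}
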