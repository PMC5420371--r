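# Standard bivariate normal probabilities.
#
# The polychoric likelihood needs Phi2(h, k, rho) for every cell corner of a
# contingency table, at every trial value of rho, so this has to be fast and
# vectorized.  We integrate the conditional-probability form
#   Phi2(h, k, rho) = int_{-inf}^{h} phi(x) Phi((k - rho x)/sqrt(1-rho^2)) dx
# with fixed Gauss-Legendre panels, splitting at the crossing point x = k/rho
# where the conditional CDF is steepest (important for |rho| near 1).

.semdif <- new.env(parent = emptyenv())

# Golub-Welsch nodes/weights for Gauss-Legendre on [-1, 1]
.gaussLegendre <- function(n) {
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = 2 * e$vectors[1L, ord]^2)
}

.glRule <- function(n = 48L) {
  key <- paste0("gl", n)
  if (is.null(.semdif[[key]])) .semdif[[key]] <- .gaussLegendre(n)
  .semdif[[key]]
}

# two-panel quadrature of the conditional form over x in [-9, h]; callers
# guarantee h <= k and finite arguments
.pbvQuad <- function(h, k, rho, gl) {
  n <- length(h)
  lo <- rep(-9, n)
  h <- pmax(h, lo)
  s <- sqrt(pmax(1 - rho^2, 1e-12))
  mid <- ifelse(abs(rho) > 1e-12, k / rho, lo)
  mid <- pmin(pmax(mid, lo), h)
  res <- numeric(n)
  for (panel in 1:2) {
    a <- if (panel == 1L) lo else mid
    b <- if (panel == 1L) mid else h
    halfw <- (b - a) / 2
    x <- outer(halfw, gl$nodes) + (a + b) / 2
    f <- dnorm(x) * pnorm((k - rho * x) / s)
    res <- res + drop(f %*% gl$weights) * halfw
  }
  res
}

#' Standard bivariate normal distribution function
#'
#' Computes \eqn{P(X \le h, Y \le k)} for standard bivariate normal
#' \eqn{(X, Y)} with correlation \code{rho}.  Vectorized over all three
#' arguments; infinite bounds are allowed.
#'
#' @param h,k upper integration limits.
#' @param rho correlation in \eqn{[-1, 1]}.
#' @return numeric vector of probabilities.
#' @export
pbvnorm <- function(h, k, rho) {
  n <- max(length(h), length(k), length(rho))
  h <- rep_len(as.numeric(h), n)
  k <- rep_len(as.numeric(k), n)
  rho <- rep_len(as.numeric(rho), n)
  stopifnot(all(abs(rho) <= 1 + 1e-12))
  rho <- pmin(pmax(rho, -1), 1)
  out <- numeric(n)

  ph <- pnorm(h)
  pk <- pnorm(k)
  done <- rep(FALSE, n)

  # degenerate correlation
  hi <- abs(rho) >= 0.99995
  if (any(hi)) {
    pos <- hi & rho > 0
    neg <- hi & rho < 0
    out[pos] <- pmin(ph[pos], pk[pos])
    out[neg] <- pmax(0, ph[neg] + pk[neg] - 1)
    done <- done | hi
  }
  # infinite / extreme bounds
  trivial <- !done & (h == Inf | k == Inf | h == -Inf | k == -Inf |
                        pmin(ph, pk) < 1e-15)
  if (any(trivial)) {
    idx <- which(trivial)
    out[idx] <- ifelse(h[idx] == Inf, pk[idx],
                ifelse(k[idx] == Inf, ph[idx],
                ifelse(h[idx] == -Inf | k[idx] == -Inf, 0,
                       0)))
    done <- done | trivial
  }

  todo <- which(!done)
  if (length(todo)) {
    gl <- .glRule(48L)
    hh <- h[todo]; kk <- k[todo]; rr <- rho[todo]
    # orient so we integrate over the smaller limit, in the left tail
    sw <- hh > kk
    tmp <- hh[sw]; hh[sw] <- kk[sw]; kk[sw] <- tmp
    flip <- hh > 0
    hq <- ifelse(flip, -hh, hh)
    rq <- ifelse(flip, -rr, rr)
    core <- .pbvQuad(hq, kk, rq, gl)
    val <- ifelse(flip, pnorm(kk) - core, core)
    # clamp to Frechet bounds against quadrature noise
    lo <- pmax(0, pnorm(hh) + pnorm(kk) - 1)
    up <- pmin(pnorm(hh), pnorm(kk))
    out[todo] <- pmin(pmax(val, lo), up)
  }
  out
}

#' Standard bivariate normal density
#'
#' @param h,k coordinates.
#' @param rho correlation, \eqn{|rho| < 1}.
#' @return numeric vector of density values; zero at infinite coordinates.
#' @export
dbvnorm <- function(h, k, rho) {
  n <- max(length(h), length(k), length(rho))
  h <- rep_len(as.numeric(h), n)
  k <- rep_len(as.numeric(k), n)
  rho <- rep_len(as.numeric(rho), n)
  s2 <- 1 - rho^2
  z <- (h^2 - 2 * rho * h * k + k^2) / s2
  out <- exp(-z / 2) / (2 * pi * sqrt(s2))
  out[!is.finite(h) | !is.finite(k)] <- 0
  out
}
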