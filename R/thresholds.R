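#' @include AllClasses.R
NULL

# Boundary handling for category counts before threshold estimation:
# empty extreme categories are collapsed into their neighbour (the category
# simply disappears, reducing the number of thresholds), interior empty
# categories receive a 0.5 pseudo-count so every threshold stays finite and
# distinct.  Returns the adjusted counts and the index mapping from original
# to collapsed categories.
.collapseCounts <- function(counts) {
  K <- length(counts)
  nonzero <- which(counts > 0)
  if (length(nonzero) < 2L)
    stop("fewer than 2 observed categories after boundary handling")
  lo <- min(nonzero)
  hi <- max(nonzero)
  kept <- counts[lo:hi]
  kept[kept == 0] <- 0.5
  map <- integer(K)
  map[seq_len(K) <= lo] <- 1L
  map[seq_len(K) >= hi] <- hi - lo + 1L
  mid <- seq_len(K) > lo & seq_len(K) < hi
  map[mid] <- which(mid) - lo + 1L
  list(counts = kept, map = map)
}

#' Estimate item thresholds from category counts
#'
#' Under the underlying-normal-variable model the threshold below category
#' \eqn{k} is \eqn{\tau_k = \Phi^{-1}} of the cumulative proportion through
#' category \eqn{k}.  Empty extreme categories are collapsed into their
#' neighbour; interior empty categories get a 0.5 pseudo-count.
#'
#' @param counts vector of per-category counts (category order 0..K-1).
#' @param item optional label used in error messages.
#' @return numeric vector of strictly increasing thresholds (length one less
#'   than the number of retained categories), with the collapsed counts and
#'   category map attached as attributes \code{"counts"} and \code{"map"}.
#' @export
estimateThresholds <- function(counts, item = NULL) {
  cc <- tryCatch(.collapseCounts(counts), error = function(e)
    stop(sprintf("item %s: %s", if (is.null(item)) "?" else item,
                 conditionMessage(e)), call. = FALSE))
  p <- cumsum(cc$counts) / sum(cc$counts)
  tau <- qnorm(p[-length(p)])
  attr(tau, "counts") <- cc$counts
  attr(tau, "map") <- cc$map
  tau
}

# least-squares fit of Phi((tau - mu)/sigma) to a group's cumulative
# proportions, used for the focal group's underlying mean/SD under equal
# (pooled) thresholds; with a single threshold sigma is fixed at 1
.fitUnderlyingMoments <- function(tau, cumprop) {
  stopifnot(length(tau) == length(cumprop))
  if (length(tau) < 2L) {
    return(c(mu = tau[1L] - qnorm(cumprop[1L]), sigma = 1))
  }
  obj <- function(par) sum((pnorm((tau - par[1L]) / exp(par[2L])) - cumprop)^2)
  # moment-matching start from probit-transformed proportions
  z <- qnorm(pmin(pmax(cumprop, 1e-6), 1 - 1e-6))
  b <- stats::coef(stats::lm(tau ~ z))
  start <- c(b[1L], log(max(b[2L], 0.2)))
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000L))
  c(mu = unname(opt$par[1L]), sigma = unname(exp(opt$par[2L])))
}
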