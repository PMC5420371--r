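#' @include AllClasses.R
NULL

#' Ordinal logistic regression DIF baseline
#'
#' Cross-method comparison baseline: a proportional-odds (cumulative logit)
#' model of the item on a trait proxy plus the violator.  The trait proxy is
#' the rest score (scale score minus the item itself) by default, which
#' avoids contaminating the proxy with the item under test; the full scale
#' score is available via \code{scoreType}.  The violator's coefficient is
#' the log odds ratio of endorsing higher categories at equal proxy level;
#' bias is flagged important when |logOR| exceeds 0.64 with p below .001.
#'
#' @param data an \linkS4class{OrdinalDataset}.
#' @param item item name (or index) under test.
#' @param violator name of a covariate, or "group" for the group label
#'   (coded 0 = reference, 1 = focal).
#' @param scoreType "rest" (default) or "total".
#' @param alpha,importanceThreshold the significance and importance gates.
#' @return list with \code{logOR}, \code{se}, \code{p}, \code{important}.
#' @export
baselineLogrDif <- function(data, item, violator, scoreType = c("rest", "total"),
                            alpha = 0.001, importanceThreshold = 0.64) {
  scoreType <- match.arg(scoreType)
  resp <- data@responses
  if (is.numeric(item)) item <- data@itemNames[item]
  y <- resp[, item]
  if (length(unique(stats::na.omit(y))) < 2L)
    stop("item ", item, " has fewer than 2 observed categories")
  v <- if (identical(violator, "group")) {
    if (is.null(data@group)) stop("no group label in the data")
    as.numeric(data@group == levels(data@group)[2L])
  } else data@covariates[[violator]]
  score <- rowSums(resp, na.rm = FALSE)
  if (scoreType == "rest") score <- score - y
  keep <- !is.na(y) & !is.na(v) & !is.na(score)
  df <- data.frame(y = factor(y[keep], ordered = TRUE), score = score[keep],
                   v = v[keep])
  fit <- MASS::polr(y ~ score + v, data = df, Hess = TRUE, method = "logistic")
  est <- stats::coef(fit)["v"]
  se <- sqrt(diag(stats::vcov(fit))["v"])
  p <- 2 * pnorm(-abs(est / se))
  list(logOR = unname(est), se = unname(se), p = unname(p),
       important = unname(abs(est) > importanceThreshold & p < alpha))
}
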