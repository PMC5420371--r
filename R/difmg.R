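#' @include semcore-fit.R
NULL

#' Multigroup Step 1: Measurement Model
#'
#' One-factor model per group with no across-group constraints; both groups
#' standardized (factor mean 0, variance 1) so all loadings, intercepts and
#' residual variances are free per group.
#'
#' @param stage1 a multigroup \linkS4class{Stage1Result}.
#' @return a \linkS4class{FitResult} (df = 28 for seven items).
#' @export
fitMeasurementModel <- function(stage1) {
  stopifnot(stage1@design == "multigroup")
  fitDwls(mgModel(length(stage1@itemNames), "measurement",
                  itemNames = stage1@itemNames), stage1)
}

#' Multigroup Step 2: No Item Bias Model
#'
#' Loadings and intercepts constrained equal across groups; the focal
#' group's factor mean and variance become identified and are freed.
#' Residual variances stay free per group — residual differences are not
#' treated as item bias and do not affect the latent difference estimate.
#'
#' @param stage1 a multigroup \linkS4class{Stage1Result}.
#' @param freeNu,freeLambda item indices exempted from equality (used by the
#'   iterative search).
#' @param start optional warm-start values.
#' @return a \linkS4class{FitResult} (df = 40 for seven items).
#' @export
fitNoBiasModel <- function(stage1, freeNu = integer(0),
                           freeLambda = integer(0), start = NULL) {
  stopifnot(stage1@design == "multigroup")
  fitDwls(mgModel(length(stage1@itemNames), "constrained", freeNu = freeNu,
                  freeLambda = freeLambda, itemNames = stage1@itemNames),
          stage1, start = start)
}

#' Effect size d of uniform item bias
#'
#' Difference in intercept parameters between the groups divided by the
#' pooled underlying-variable standard deviation.  Benchmarks 0.2 / 0.5 /
#' 0.8 for small / medium / large; positive values mean the focal group
#' endorses the item more highly at equal trait level.
#'
#' @param nuRef,nuFoc intercept estimates per group.
#' @param sdPooled pooled underlying SD, \eqn{\sqrt{(\sigma^2_{ref} +
#'   \sigma^2_{foc})/2}}.
#' @return signed effect size d.
#' @export
effectSizeUniform <- function(nuRef, nuFoc, sdPooled) {
  stopifnot(sdPooled > 0)
  (nuFoc - nuRef) / sdPooled
}

#' Effect size d of nonuniform item bias
#'
#' Default (\code{magnitude = "mean-impact"}): difference in loadings
#' multiplied by the difference in common factor means between the groups,
#' divided by the pooled underlying SD — the mean impact a loading
#' difference has on the item given the groups' latent separation.  By this
#' definition the effect is zero when latent means are equal, however
#' different the loadings; \code{magnitude = "loading-sd"} offers
#' \eqn{\Delta\lambda \cdot sd(T) / sd_{pooled}} as an alternative magnitude
#' for that situation, but is never used by the reporting pipeline.
#'
#' @param lambdaRef,lambdaFoc loading estimates per group.
#' @param kappaRef,kappaFoc factor mean estimates per group.
#' @param sdPooled pooled underlying SD.
#' @param magnitude "mean-impact" (default) or "loading-sd".
#' @param factorSd factor SD used by the "loading-sd" magnitude.
#' @return signed effect size d.
#' @export
effectSizeNonuniform <- function(lambdaRef, lambdaFoc, kappaRef, kappaFoc,
                                 sdPooled,
                                 magnitude = c("mean-impact", "loading-sd"),
                                 factorSd = 1) {
  stopifnot(sdPooled > 0)
  magnitude <- match.arg(magnitude)
  if (magnitude == "mean-impact")
    (lambdaFoc - lambdaRef) * (kappaFoc - kappaRef) / sdPooled
  else
    (lambdaFoc - lambdaRef) * factorSd / sdPooled
}

# pooled model-implied underlying SD of one item (reference variance is 1
# by the identification convention)
.pooledItemSd <- function(fit, item) {
  vFoc <- fit@implied[paste0("var.f:", item)]
  sqrt((1 + vFoc) / 2)
}

#' Multigroup Step 3: iterative item-bias search
#'
#' Greedy forward search: every still-constrained cross-group intercept or
#' loading equality is released one at a time, the candidate giving the
#' largest chi-square improvement is accepted if its 1-df difference test
#' has p below \code{alpha}, and the search repeats until no candidate is
#' significant.  A freed parameter stays free.  Ties break to the lower
#' item index, intercept before loading.  When the current model reaches
#' fit equivalent to the Measurement Model this is logged, but the candidate
#' scan continues until the significance rule stops it.
#'
#' @param stage1 a multigroup \linkS4class{Stage1Result}.
#' @param noBias,measurement parent fits from Steps 1-2 (refitted if
#'   missing).
#' @param alpha significance gate for the 1-df difference tests
#'   (default .001).
#' @return list with \code{findings} (data.frame), \code{finalFit},
#'   \code{trail} (accepted intermediate fits), \code{log}.
#' @export
iterativeBiasSearch <- function(stage1, noBias = NULL, measurement = NULL,
                                alpha = 0.001) {
  if (is.null(measurement)) measurement <- fitMeasurementModel(stage1)
  if (is.null(noBias)) noBias <- fitNoBiasModel(stage1)
  items <- stage1@itemNames
  p <- length(items)
  freeNu <- integer(0)
  freeLambda <- integer(0)
  current <- noBias
  log <- character(0)
  trail <- list()
  findings <- data.frame(item = character(0), violator = character(0),
                         type = character(0), chisqDiff = numeric(0),
                         dfDiff = integer(0), p = numeric(0),
                         step = integer(0))
  step <- 0L
  repeat {
    # candidate order fixes the tie-break: intercepts first, low item first
    cand <- rbind(
      data.frame(item = setdiff(seq_len(p), freeNu), type = "uniform"),
      data.frame(item = setdiff(seq_len(p), freeLambda), type = "nonuniform"))
    if (!nrow(cand)) break
    fits <- vector("list", nrow(cand))
    improv <- rep(-Inf, nrow(cand))
    for (ci in seq_len(nrow(cand))) {
      fN <- if (cand$type[ci] == "uniform") c(freeNu, cand$item[ci]) else freeNu
      fL <- if (cand$type[ci] == "nonuniform") c(freeLambda, cand$item[ci]) else freeLambda
      f <- tryCatch(fitNoBiasModel(stage1, freeNu = fN, freeLambda = fL,
                                   start = current@estimates),
                    error = function(e) NULL)
      if (is.null(f) || !f@converged) {
        log <- c(log, sprintf("step %d: candidate %s/%s skipped (no convergence)",
                              step + 1L, items[cand$item[ci]], cand$type[ci]))
        next
      }
      fits[[ci]] <- f
      improv[ci] <- scaledChisqDiffTest(current, f, alpha = alpha)$diff
    }
    best <- which.max(improv)
    if (!is.finite(improv[best])) break
    test <- scaledChisqDiffTest(current, fits[[best]], alpha = alpha)
    log <- c(log, sprintf(
      "step %d: best candidate %s (%s), chisq diff %.2f (1 df), p = %.3g%s",
      step + 1L, items[cand$item[best]], cand$type[best], test$diff, test$p,
      if (test$nonMonotone) " [non-monotone]" else ""))
    if (!test$significant) {
      log <- c(log, sprintf("step %d: no significant candidate; search stops",
                            step + 1L))
      break
    }
    step <- step + 1L
    if (cand$type[best] == "uniform") freeNu <- c(freeNu, cand$item[best])
    else freeLambda <- c(freeLambda, cand$item[best])
    current <- fits[[best]]
    trail[[sprintf("search step %d", step)]] <- current
    findings <- rbind(findings, data.frame(
      item = items[cand$item[best]], violator = "group",
      type = cand$type[best], chisqDiff = test$diff, dfDiff = 1L,
      p = test$p, step = step))
    eq <- chisqDiffTest(current, measurement, alpha = alpha)
    if (!eq$significant)
      log <- c(log, sprintf(
        "step %d: current model fit is equivalent to the Measurement Model (p = %.3g); scan continues",
        step, eq$p))
  }
  list(findings = findings, finalFit = current, trail = trail, log = log,
       freeNu = freeNu, freeLambda = freeLambda)
}

#' Multigroup Step 4: true latent group difference
#'
#' Standardized difference in common factor means,
#' \eqn{d = \kappa_{foc} / \sqrt{(\phi_{ref} + \phi_{foc})/2}} with the
#' reference mean fixed at zero, from both the Final Model (adjusted for
#' detected bias) and the No-Item-Bias Model (unadjusted); the p value is
#' the Wald test of the focal factor mean.
#'
#' @param final,noBias \linkS4class{FitResult}s of the Final and
#'   No-Item-Bias models.
#' @return data.frame with columns context, d, kappa, se, p.
#' @export
trueDifference <- function(final, noBias) {
  one <- function(fit, context) {
    kap <- fit@estimates["kappa.foc"]
    phi <- fit@estimates["phi.foc"]
    se <- fit@robustSes["kappa.foc"]
    data.frame(context = context,
               d = unname(kap / sqrt((1 + phi) / 2)),
               kappa = unname(kap), se = unname(se),
               p = unname(2 * pnorm(-abs(kap / se))))
  }
  rbind(one(final, "adjusted"), one(noBias, "unadjusted"))
}

#' Full multigroup item-bias procedure
#'
#' Runs Stage 1 and the four-step multigroup sequence (Measurement Model,
#' No-Item-Bias Model, iterative bias search, true-difference estimation)
#' and assembles a \linkS4class{DifReport}.  Effect sizes of the detected
#' biases are computed from the Final Model; a finding is flagged important
#' when |d| exceeds \code{importanceThreshold} (and is, by construction,
#' significant at \code{alpha}).
#'
#' @param data an \linkS4class{OrdinalDataset} with a two-level group.
#' @param alpha significance gate (default .001).
#' @param importanceThreshold importance gate on |d| (default 0.2).
#' @param stage1 optionally a precomputed \linkS4class{Stage1Result}.
#' @return a \linkS4class{DifReport}.
#' @export
runMultigroupDif <- function(data, alpha = 0.001, importanceThreshold = 0.2,
                             stage1 = NULL) {
  if (is.null(stage1)) stage1 <- runStage1(data, design = "multigroup")
  measurement <- fitMeasurementModel(stage1)
  noBias <- fitNoBiasModel(stage1)
  log <- c(sprintf("Measurement Model: chisq %.2f, df %d, RMSEA %.3f",
                   measurement@chisq, measurement@df, measurement@rmsea),
           sprintf("No Item Bias Model: chisq %.2f, df %d, RMSEA %.3f",
                   noBias@chisq, noBias@df, noBias@rmsea))
  presence <- chisqDiffTest(noBias, measurement, alpha = alpha)
  log <- c(log, sprintf(
    "presence test (No-Item-Bias vs Measurement): diff %.2f, df %d, p = %.3g",
    presence$diff, presence$dfDiff, presence$p))
  if (presence$significant) {
    sr <- iterativeBiasSearch(stage1, noBias, measurement, alpha = alpha)
  } else {
    log <- c(log, "no indication of item bias; Final Model = No Item Bias Model")
    sr <- list(findings = data.frame(item = character(0), violator = character(0),
                                     type = character(0), chisqDiff = numeric(0),
                                     dfDiff = integer(0), p = numeric(0),
                                     step = integer(0)),
               finalFit = noBias, trail = list(), log = character(0))
  }
  log <- c(log, sr$log)
  final <- sr$finalFit
  findings <- sr$findings
  if (nrow(findings)) {
    es <- numeric(nrow(findings))
    for (i in seq_len(nrow(findings))) {
      it <- findings$item[i]
      sdp <- .pooledItemSd(final, it)
      es[i] <- if (findings$type[i] == "uniform") {
        effectSizeUniform(0, final@estimates[paste0("nu.foc.", it)], sdp)
      } else {
        effectSizeNonuniform(final@estimates[paste0("lambda.", it)],
                             final@estimates[paste0("lambda.foc.", it)],
                             0, final@estimates["kappa.foc"], sdp)
      }
    }
    findings$effectSize <- unname(es)
    findings$important <- abs(findings$effectSize) > importanceThreshold &
      findings$p < alpha
  } else {
    findings$effectSize <- numeric(0)
    findings$important <- logical(0)
  }
  trail <- c(list("Measurement Model" = measurement,
                  "No Item Bias Model" = noBias),
             sr$trail)
  trail[["Final Model"]] <- final
  new("DifReport", procedure = "multigroup", findings = findings,
      modelTrail = trail,
      trueDifference = trueDifference(final, noBias),
      associations = data.frame(),
      flaggedPairs = stage1@flaggedPairs, log = log)
}
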