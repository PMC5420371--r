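#' @include AllClasses.R
NULL

#' Accessors
#'
#' Small accessor generics for the package's S4 containers.
#'
#' @param object an object from this package.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("itemNames", function(object) standardGeneric("itemNames"))
#' @rdname accessors
#' @export
setMethod("itemNames", "GeneratorSpec", function(object) object@itemNames)
#' @rdname accessors
#' @export
setMethod("itemNames", "OrdinalDataset", function(object) object@itemNames)
#' @rdname accessors
#' @export
setMethod("itemNames", "Stage1Result", function(object) object@itemNames)

#' @rdname accessors
#' @export
setGeneric("nItems", function(object) standardGeneric("nItems"))
#' @rdname accessors
#' @export
setMethod("nItems", "GeneratorSpec", function(object) object@nItems)
#' @rdname accessors
#' @export
setMethod("nItems", "OrdinalDataset", function(object) ncol(object@responses))

#' @rdname accessors
#' @export
setGeneric("responses", function(object) standardGeneric("responses"))
#' @rdname accessors
#' @export
setMethod("responses", "OrdinalDataset", function(object) object@responses)

#' @rdname accessors
#' @export
setGeneric("groupLabels", function(object) standardGeneric("groupLabels"))
#' @rdname accessors
#' @export
setMethod("groupLabels", "OrdinalDataset", function(object) object@group)

#' @rdname accessors
#' @export
setGeneric("covariates", function(object) standardGeneric("covariates"))
#' @rdname accessors
#' @export
setMethod("covariates", "OrdinalDataset", function(object) object@covariates)

#' @rdname accessors
#' @export
setGeneric("thresholds", function(object) standardGeneric("thresholds"))
#' @rdname accessors
#' @export
setMethod("thresholds", "Stage1Result", function(object) object@thresholds)

#' @rdname accessors
#' @export
setGeneric("correlations", function(object) standardGeneric("correlations"))
#' @rdname accessors
#' @export
setMethod("correlations", "Stage1Result", function(object) object@correlations)

#' @rdname accessors
#' @export
setGeneric("underlyingMeans", function(object) standardGeneric("underlyingMeans"))
#' @rdname accessors
#' @export
setMethod("underlyingMeans", "Stage1Result", function(object) object@underlyingMeans)

#' @rdname accessors
#' @export
setGeneric("underlyingSds", function(object) standardGeneric("underlyingSds"))
#' @rdname accessors
#' @export
setMethod("underlyingSds", "Stage1Result", function(object) object@underlyingSds)

#' @rdname accessors
#' @export
setGeneric("flaggedPairs", function(object) standardGeneric("flaggedPairs"))
#' @rdname accessors
#' @export
setMethod("flaggedPairs", "Stage1Result", function(object) object@flaggedPairs)
#' @rdname accessors
#' @export
setMethod("flaggedPairs", "DifReport", function(object) object@flaggedPairs)

#' @rdname accessors
#' @export
setGeneric("estimates", function(object) standardGeneric("estimates"))
#' @rdname accessors
#' @export
setMethod("estimates", "FitResult", function(object) object@estimates)

#' @rdname accessors
#' @export
setGeneric("robustSes", function(object) standardGeneric("robustSes"))
#' @rdname accessors
#' @export
setMethod("robustSes", "FitResult", function(object) object@robustSes)

#' @rdname accessors
#' @export
setGeneric("findings", function(object) standardGeneric("findings"))
#' @rdname accessors
#' @export
setMethod("findings", "DifReport", function(object) object@findings)

#' @rdname accessors
#' @export
setGeneric("modelTrail", function(object) standardGeneric("modelTrail"))
#' @rdname accessors
#' @export
setMethod("modelTrail", "DifReport", function(object) object@modelTrail)

#' @rdname accessors
#' @export
setGeneric("trueDifferences", function(object) standardGeneric("trueDifferences"))
#' @rdname accessors
#' @export
setMethod("trueDifferences", "DifReport", function(object) object@trueDifference)

#' @rdname accessors
#' @export
setGeneric("associations", function(object) standardGeneric("associations"))
#' @rdname accessors
#' @export
setMethod("associations", "DifReport", function(object) object@associations)

#' Model degrees of freedom
#'
#' Counts df of a declared model as (modeled moments) minus (free parameter
#' equality classes).  Per group the modeled moments are the p underlying
#' means plus the p(p+1)/2 variances/covariances of the observed variables.
#'
#' @param model a \linkS4class{ModelSpec}.
#' @return integer degrees of freedom.
#' @export
setGeneric("countDf", function(model) standardGeneric("countDf"))

# show methods ---------------------------------------------------------------

setMethod("show", "GeneratorSpec", function(object) {
  cat(sprintf("GeneratorSpec: %d items x %d categories, %d group(s), %d factor(s)\n",
              object@nItems, object@nCategories, object@nGroups,
              length(unique(object@itemFactor))))
  if (length(object@violators))
    cat("  violators:", paste(vapply(object@violators, `[[`, "", "name"),
                              collapse = ", "), "\n")
  cat(sprintf("  injected bias terms: %d\n", nrow(object@difDefs)))
})

setMethod("show", "OrdinalDataset", function(object) {
  cat(sprintf("OrdinalDataset: %d respondents x %d items (categories 0..%d)\n",
              nrow(object@responses), ncol(object@responses),
              object@nCategories - 1L))
  if (!is.null(object@group))
    cat("  groups:", paste(sprintf("%s (n=%d)", levels(object@group),
                                   table(object@group)), collapse = ", "), "\n")
  if (ncol(object@covariates))
    cat("  covariates:", paste(names(object@covariates), collapse = ", "), "\n")
})

setMethod("show", "Stage1Result", function(object) {
  cat(sprintf("Stage1Result (%s): %d items, n = %s\n", object@design,
              length(object@itemNames),
              paste(object@nPerGroup, collapse = " + ")))
  cat(sprintf("  %d stacked moments; %d pair(s) flagged for non-normality\n",
              length(object@moments), nrow(object@flaggedPairs)))
})

setMethod("show", "ModelSpec", function(object) {
  if (object@family == "mg") {
    cat(sprintf("ModelSpec (multigroup, %s): %d items, 2 groups\n",
                object@variant, object@nItems))
    if (length(object@freeNu))
      cat("  intercepts freed:", paste(object@itemNames[object@freeNu],
                                       collapse = ", "), "\n")
    if (length(object@freeLambda))
      cat("  loadings freed:", paste(object@itemNames[object@freeLambda],
                                     collapse = ", "), "\n")
  } else {
    cat(sprintf("ModelSpec (multidimensional): %d items, %d factor(s), %d violator(s)\n",
                object@nItems, length(unique(object@itemFactor)),
                length(object@violatorNames)))
    if (nrow(object@freeDirect))
      cat("  direct effects freed:",
          paste(sprintf("%s<-%s", object@itemNames[object@freeDirect[, 1L]],
                        object@violatorNames[object@freeDirect[, 2L]]),
                collapse = ", "), "\n")
  }
  cat("  df =", countDf(object), "\n")
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: chisq = %.3f, df = %d, p %s, RMSEA = %.3f [%.3f; %.3f]%s\n",
              object@chisq, object@df,
              if (object@pValue < 0.001) "< .001" else sprintf("= %.3f", object@pValue),
              object@rmsea, object@rmseaCi[1L], object@rmseaCi[2L],
              if (object@converged) "" else " (NOT converged)"))
})

setMethod("show", "DifReport", function(object) {
  cat(sprintf("DifReport (%s procedure): %d finding(s)\n", object@procedure,
              nrow(object@findings)))
  if (nrow(object@findings)) {
    f <- object@findings
    for (i in seq_len(nrow(f)))
      cat(sprintf("  %d. %s bias of %s w.r.t. %s: effect size %.3f%s\n",
                  i, f$type[i], f$item[i], f$violator[i], f$effectSize[i],
                  if (f$important[i]) " (important)" else ""))
  }
  if (nrow(object@trueDifference)) {
    td <- object@trueDifference
    for (i in seq_len(nrow(td)))
      cat(sprintf("  true difference (%s): d = %.3f (p %s)\n", td$context[i],
                  td$d[i],
                  if (td$p[i] < 0.001) "< .001" else sprintf("= %.3f", td$p[i])))
  }
})
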