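#' @include AllClasses.R
NULL

#' Read an ordinal dataset from CSV
#'
#' One row per respondent; item columns hold integer categories, with
#' optional group and covariate columns.
#'
#' @param path CSV file path.
#' @param items item column names (default: all columns not named as group
#'   or covariates).
#' @param group optional group column name (two levels; the level that
#'   appears first in the file is the reference group).
#' @param covariateNames optional numeric covariate columns.
#' @param missingCode value to treat as missing in item columns (besides
#'   NA).
#' @return an \linkS4class{OrdinalDataset}.
#' @export
readOrdinalData <- function(path, items = NULL, group = NULL,
                            covariateNames = character(0), missingCode = NA) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (is.null(items)) items <- setdiff(names(df), c(group, covariateNames))
  missing <- setdiff(c(items, group, covariateNames), names(df))
  if (length(missing))
    stop("columns not found in ", path, ": ", paste(missing, collapse = ", "))
  resp <- as.matrix(df[, items, drop = FALSE])
  if (!is.na(missingCode)) resp[resp == missingCode] <- NA
  storage.mode(resp) <- "integer"
  new("OrdinalDataset", responses = resp,
      group = if (!is.null(group))
        factor(df[[group]], levels = unique(df[[group]])) else NULL,
      covariates = df[, covariateNames, drop = FALSE],
      itemNames = items,
      nCategories = as.integer(max(resp, na.rm = TRUE)) + 1L)
}

#' Write an ordinal dataset to CSV
#'
#' @param data an \linkS4class{OrdinalDataset}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeOrdinalData <- function(data, path) {
  df <- as.data.frame(data@responses)
  if (!is.null(data@group)) df$group <- as.character(data@group)
  if (ncol(data@covariates)) df <- cbind(df, data@covariates)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a generating specification to YAML (provenance record)
#'
#' @param spec a \linkS4class{GeneratorSpec}.
#' @param path output YAML path.
#' @return the path, invisibly.
#' @export
writeGeneratorSpec <- function(spec, path) {
  obj <- list(
    nItems = spec@nItems, nCategories = spec@nCategories,
    nGroups = spec@nGroups, itemFactor = spec@itemFactor,
    loadings = asplit(spec@loadings, 1L),
    intercepts = asplit(spec@intercepts, 1L),
    residualSds = spec@residualSds, thresholds = spec@thresholds,
    factorMeans = asplit(spec@factorMeans, 1L),
    factorSds = asplit(spec@factorSds, 1L),
    factorCorr = spec@factorCorr, violators = spec@violators,
    difDefs = if (nrow(spec@difDefs)) asplit(spec@difDefs, 1L) else list(),
    itemNames = spec@itemNames)
  yaml::write_yaml(lapply(obj, function(x)
    if (is.list(x)) lapply(x, function(e) as.list(e)) else x), path)
  invisible(path)
}

#' Serialize a model specification to/from YAML
#'
#' @param model a \linkS4class{ModelSpec}.
#' @param path YAML file path.
#' @return \code{writeModelSpec}: the path, invisibly;
#'   \code{readModelSpec}: a \linkS4class{ModelSpec}.
#' @export
writeModelSpec <- function(model, path) {
  yaml::write_yaml(list(
    family = model@family, variant = model@variant,
    nItems = model@nItems, nGroups = model@nGroups,
    itemFactor = model@itemFactor,
    freeNu = model@freeNu, freeLambda = model@freeLambda,
    violatorNames = model@violatorNames,
    freeDirect = if (nrow(model@freeDirect))
      lapply(seq_len(nrow(model@freeDirect)), function(r)
        as.list(model@freeDirect[r, ])) else list(),
    thetaEqual = model@thetaEqual,
    itemNames = model@itemNames), path)
  invisible(path)
}

#' @rdname writeModelSpec
#' @export
readModelSpec <- function(path) {
  o <- yaml::read_yaml(path)
  fd <- if (length(o$freeDirect))
    do.call(rbind, lapply(o$freeDirect, unlist)) else matrix(0L, 0L, 2L)
  if (identical(o$family, "mg")) {
    mgModel(o$nItems, o$variant, freeNu = unlist(o$freeNu) %||% integer(0),
            freeLambda = unlist(o$freeLambda) %||% integer(0),
            thetaEqual = isTRUE(o$thetaEqual), itemNames = o$itemNames)
  } else {
    mdModel(o$nItems, unlist(o$itemFactor),
            violatorNames = unlist(o$violatorNames) %||% character(0),
            freeDirect = fd, itemNames = o$itemNames)
  }
}

#' Serialize a fit result to JSON
#'
#' Writes the fit summary (chi-square, df, p, RMSEA with interval,
#' convergence) and the parameter table (name, estimate, robust SE, z).
#'
#' @param fit a \linkS4class{FitResult}.
#' @param path JSON file path.
#' @return the path, invisibly.
#' @export
writeFitResult <- function(fit, path) {
  free <- names(fit@robustSes)
  params <- data.frame(name = names(fit@estimates),
                       estimate = unname(fit@estimates))
  params$robustSe <- fit@robustSes[params$name]
  params$z <- params$estimate / params$robustSe
  jsonlite::write_json(list(
    chisq = fit@chisq, df = fit@df, p = fit@pValue,
    rmsea = fit@rmsea, rmseaLo90 = fit@rmseaCi[1L],
    rmseaHi90 = fit@rmseaCi[2L], converged = fit@converged,
    nTotal = fit@nTotal, nGroups = fit@nGroups,
    parameters = params), path, auto_unbox = TRUE, digits = NA,
    dataframe = "rows", na = "null")
  invisible(path)
}

#' Serialize Stage 1 results to JSON
#'
#' Matrices are written row-major with their labels.
#'
#' @param stage1 a \linkS4class{Stage1Result}.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeStage1 <- function(stage1, path) {
  obj <- list(
    design = stage1@design, items = stage1@itemNames,
    covariates = stage1@covariateNames,
    thresholds = stats::setNames(stage1@thresholds, stage1@itemNames),
    correlations = stage1@correlations,
    underlyingMeans = stage1@underlyingMeans,
    underlyingSds = stage1@underlyingSds,
    pairRmsea = stage1@pairRmsea,
    flaggedPairs = stage1@flaggedPairs,
    moments = as.list(stage1@moments),
    acov = stage1@acov,
    nPerGroup = stage1@nPerGroup, groupLevels = stage1@groupLevels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

# findings table in the layout of the published comparison tables:
# item, bias type, effect size, importance flag
.findingsTable <- function(report) {
  f <- report@findings
  if (!nrow(f))
    return(data.frame(item = character(0), violator = character(0),
                      type = character(0), effectSize = numeric(0),
                      p = numeric(0), important = logical(0)))
  data.frame(item = f$item, violator = f$violator, type = f$type,
             effectSize = f$effectSize, p = f$p, important = f$important)
}

.trailTable <- function(report) {
  tr <- report@modelTrail
  base <- report@modelTrail[["Measurement Model"]]
  do.call(rbind, lapply(names(tr), function(nm) {
    f <- tr[[nm]]
    cmp <- if (!identical(nm, "Measurement Model")) {
      tst <- chisqDiffTest(f, base)
      sprintf("vs Measurement: diff %.2f, df %d, p %.3g",
              tst$diff, tst$dfDiff, tst$p)
    } else ""
    data.frame(model = nm, df = f@df, chisq = f@chisq, p = f@pValue,
               rmsea = f@rmsea, rmseaLo90 = f@rmseaCi[1L],
               rmseaHi90 = f@rmseaCi[2L], converged = f@converged,
               comparison = cmp)
  }))
}

#' Write a DIF report to disk
#'
#' Produces \code{report.json} (findings, model trail, true differences /
#' associations, search log), \code{findings.tsv} (item, bias type, effect
#' size, importance), and \code{models.tsv} (model, df, chi-square, p,
#' RMSEA with interval, comparison against the Measurement Model).
#'
#' @param report a \linkS4class{DifReport}.
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
writeDifReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trail <- .trailTable(report)
  obj <- list(
    procedure = report@procedure,
    limitations = if (report@procedure == "multidimensional")
      "nonuniform (violator-by-trait interaction) bias is not investigated by the multidimensional procedure"
    else NULL,
    findings = .findingsTable(report),
    models = trail,
    trueDifference = report@trueDifference,
    associations = report@associations,
    flaggedPairs = report@flaggedPairs,
    log = report@log)
  jsonPath <- file.path(dir, "report.json")
  jsonlite::write_json(obj[!vapply(obj, is.null, TRUE)], jsonPath,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  findingsPath <- file.path(dir, "findings.tsv")
  utils::write.table(.findingsTable(report), findingsPath, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  modelsPath <- file.path(dir, "models.tsv")
  utils::write.table(trail, modelsPath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(report = jsonPath, findings = findingsPath, models = modelsPath))
}
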