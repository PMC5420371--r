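test_that("the logistic baseline is null-calibrated and sign-consistent", {
  d <- simulateOrdinal(makeHadsLikeSpec("no_dif"), 2000, seed = 1001)
  b <- baselineLogrDif(d, "item2", "group")
  expect_lt(abs(b$logOR), 0.15)
  expect_false(b$important)
  # flipping the violator coding flips the log odds ratio exactly
  dFlip <- new("OrdinalDataset", responses = responses(d),
               group = factor(groupLabels(d),
                              levels = c("focal", "ref")),
               covariates = covariates(d), itemNames = itemNames(d),
               nCategories = 4L)
  bFlip <- baselineLogrDif(dFlip, "item2", "group")
  expect_equal(bFlip$logOR, -b$logOR, tolerance = 1e-3)
})

test_that("the baseline recovers a cumulative-logit bias of known size", {
  # data generated from the fitted model's own process: ordinal item with
  # linear predictor eta = 1.2 * trait + logOR * v
  set.seed(1002)
  n <- 3000
  trait <- rnorm(n)
  v <- rbinom(n, 1, 0.5)
  eta <- 1.2 * trait + 1.0 * v
  cuts <- c(-1.5, 0, 1.5)
  u <- runif(n)
  item <- rowSums(u > plogis(outer(-eta, cuts, "+")))
  # companion items give the rest score a trait signal
  others <- vapply(1:4, function(j)
    findInterval(0.8 * trait + 0.6 * rnorm(n), tauQuartile), numeric(n))
  resp <- cbind(item, others)
  colnames(resp) <- paste0("it", 1:5)
  storage.mode(resp) <- "integer"
  d <- new("OrdinalDataset", responses = resp, group = NULL,
           covariates = data.frame(v = v), itemNames = colnames(resp),
           nCategories = 4L)
  b <- baselineLogrDif(d, "it1", "v")
  expect_gt(b$logOR, 0.7)
  expect_lt(b$logOR, 1.3)
  expect_true(b$important)
  # the total-score variant self-contaminates, but stays in the ballpark
  bTot <- baselineLogrDif(d, "it1", "v", scoreType = "total")
  expect_gt(bTot$logOR, 0.4)
})

test_that("simulate mode writes deterministic artifacts", {
  out1 <- file.path(tempdir(), "sim1")
  out2 <- file.path(tempdir(), "sim2")
  suppressMessages({
    runDif(list(mode = "simulate", scenario = "one_factor_7",
                nPerGroup = 80, seed = 5, out = out1))
    runDif(list(mode = "simulate", scenario = "one_factor_7",
                nPerGroup = 80, seed = 5, out = out2))
  })
  f1 <- file.path(out1, "one_factor_7.csv")
  f2 <- file.path(out2, "one_factor_7.csv")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(f2))
  expect_true(file.exists(file.path(out1, "one_factor_7.yaml")))
})

test_that("mg mode writes a coherent report bundle", {
  dir <- file.path(tempdir(), "mgrun")
  csv <- file.path(tempdir(), "mg.csv")
  writeOrdinalData(simulateOrdinal(makeHadsLikeSpec("no_dif"), 500,
                                   seed = 1003), csv)
  suppressMessages(
    rep <- runDif(list(mode = "mg", input = csv,
                       items = paste0("item", 1:7), group = "group",
                       out = dir)))
  expect_s4_class(rep, "DifReport")
  found <- utils::read.delim(file.path(dir, "findings.tsv"))
  expect_identical(nrow(found), 0L)
  models <- utils::read.delim(file.path(dir, "models.tsv"))
  expect_identical(nrow(models), 3L)
  # df column must agree with countDf recomputed from the model specs
  expect_identical(models$df,
                   vapply(modelTrail(rep), function(f) countDf(f@model),
                          integer(1), USE.NAMES = FALSE))
  js <- jsonlite::read_json(file.path(dir, "report.json"),
                            simplifyVector = TRUE)
  expect_identical(js$procedure, "multigroup")
  expect_identical(nrow(js$models), 3L)
})

test_that("report tables round-trip through JSON without loss", {
  d <- simulateOrdinal(makeHadsLikeSpec("uniform_dif"), 1000, seed = 1004)
  rep <- runMultigroupDif(d)
  dir <- file.path(tempdir(), "rt")
  writeDifReport(rep, dir)
  js <- jsonlite::read_json(file.path(dir, "report.json"),
                            simplifyVector = TRUE)
  f <- findings(rep)
  expect_identical(js$findings$item, f$item)
  expect_identical(js$findings$type, f$type)
  expect_equal(js$findings$effectSize, f$effectSize)
  expect_identical(js$findings$important, f$important)
  tsv <- utils::read.delim(file.path(dir, "findings.tsv"))
  expect_equal(tsv$effectSize, f$effectSize)
  expect_identical(tsv$item, f$item)
})

test_that("model specifications and fit results serialize losslessly", {
  m <- mdModel(14, rep(1:2, each = 7), c("gender", "age"),
               freeDirect = rbind(c(4L, 2L), c(9L, 1L)))
  yml <- tempfile(fileext = ".yaml")
  writeModelSpec(m, yml)
  m2 <- readModelSpec(yml)
  expect_identical(countDf(m2), countDf(m))
  expect_identical(m2@freeDirect, m@freeDirect)
  expect_identical(m2@violatorNames, m@violatorNames)

  mg <- mgModel(7, "constrained", freeNu = 3L, thetaEqual = TRUE)
  writeModelSpec(mg, yml)
  expect_identical(countDf(readModelSpec(yml)), countDf(mg))

  f <- fitDwls(mgModel(7, "constrained"), nullStage1()$stage1)
  js <- tempfile(fileext = ".json")
  writeFitResult(f, js)
  o <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_identical(o$df, f@df)
  expect_equal(o$chisq, f@chisq)
  i <- match("kappa.foc", o$parameters$name)
  expect_equal(o$parameters$estimate[i], unname(estimates(f)["kappa.foc"]))
  expect_equal(o$parameters$robustSe[i], unname(robustSes(f)["kappa.foc"]))
})

test_that("configuration validation catches bad inputs", {
  expect_error(runDif(list(mode = "fly")), "mode must be")
  expect_error(runDif(list(mode = "mg", alpha = 2)), "alpha")
  expect_error(runDif(list(mode = "mg")), "input")
  expect_error(runDif(list(mode = "md", input = "x.csv",
                           importanceR = -1)), "importance")
})
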