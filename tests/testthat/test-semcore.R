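# degrees-of-freedom accounting ----------------------------------------------

test_that("countDf reproduces the published model accounting", {
  # multigroup, 7 items: measurement 28; full invariance 40; finals 38/37/34
  expect_identical(countDf(mgModel(7, "measurement")), 28L)
  expect_identical(countDf(mgModel(7, "constrained")), 40L)
  expect_identical(countDf(mgModel(7, "constrained", freeNu = c(2, 6))), 38L)
  expect_identical(countDf(mgModel(7, "constrained", freeNu = c(1, 7),
                                   freeLambda = 3)), 37L)
  expect_identical(countDf(mgModel(7, "constrained", freeNu = c(2, 3, 5, 7),
                                   freeLambda = c(2, 6))), 34L)
  # multidimensional, 14 items + 2 violators: 76; 100; 88 after 12 effects
  expect_identical(countDf(mdModel(14, rep(1:2, each = 7))), 76L)
  expect_identical(countDf(mdModel(14, rep(1:2, each = 7),
                                   c("gender", "age"))), 100L)
  expect_identical(countDf(mdModel(14, rep(1:2, each = 7), c("gender", "age"),
                                   freeDirect = cbind(1:12, rep(1:2, 6)))), 88L)
})

test_that("equal residual variances are a config switch, never a default", {
  # one shared residual class per item instead of two: 7 fewer parameters
  expect_identical(countDf(mgModel(7, "constrained", thetaEqual = TRUE)), 47L)
  f <- fitDwls(mgModel(7, "constrained", thetaEqual = TRUE),
               nullStage1()$stage1)
  expect_true(f@converged)
  expect_identical(f@df, 47L)
  lam <- estimates(f)[paste0("lambda.item", 1:7)]
  expect_equal(unname(estimates(f)[paste0("theta.foc.item", 1:7)]),
               unname(1 - lam^2))
})

test_that("over-parameterized declarations are rejected", {
  expect_error(countDf(mgModel(1, "measurement")), "negative degrees")
})

# RMSEA arithmetic ------------------------------------------------------------

test_that("rmseaWithCi reproduces the published fit table", {
  r <- rmseaWithCi(50.64, 28, 1068, 2)
  expect_identical(round(r$rmsea, 3), 0.039)
  expect_identical(round(r$lo90, 3), 0.021)
  expect_identical(round(r$hi90, 3), 0.056)
  expect_identical(round(rmseaWithCi(126.4, 40, 1068, 2)$rmsea, 3), 0.064)
  expect_identical(round(rmseaWithCi(485.05, 76, 1068, 1)$rmsea, 3), 0.071)
  expect_identical(round(rmseaWithCi(1029.8, 100, 1068, 1)$rmsea, 3), 0.093)
})

test_that("rmsea truncates at zero and rejects df = 0", {
  r <- rmseaWithCi(28, 28, 500, 2)
  expect_identical(r$rmsea, 0)
  expect_identical(r$lo90, 0)
  expect_error(rmseaWithCi(10, 0, 500), "df = 0")
})

# chi-square difference bookkeeping -------------------------------------------

test_that("chisqDiffTest does the published bookkeeping", {
  d <- chisqDiffTest(list(chisq = 126.4, df = 40L),
                     list(chisq = 50.64, df = 28L))
  expect_equal(d$diff, 75.76)
  expect_identical(d$dfDiff, 12L)
  expect_true(d$significant)
  # identical fit: zero difference, p = 1 on any extra df
  d0 <- chisqDiffTest(list(chisq = 50, df = 30L), list(chisq = 50, df = 28L))
  expect_identical(d0$p, pchisq(0, 2, lower.tail = FALSE))
  # non-monotone pairs are flagged, not hidden
  dn <- chisqDiffTest(list(chisq = 49, df = 30L), list(chisq = 50, df = 28L))
  expect_true(dn$nonMonotone)
  expect_identical(dn$p, 1)
  expect_error(chisqDiffTest(list(chisq = 50, df = 28L),
                             list(chisq = 40, df = 28L)), "larger df")
})

# DWLS fitting ----------------------------------------------------------------

test_that("a just-identified model reproduces the moments exactly", {
  # 3 items, two-group measurement model: 12 fitted moments, 12 parameters
  spec <- makeGeneratorSpec(3L, nGroups = 2L, loadings = c(0.7, 0.6, 0.8),
                            thresholds = rep(list(tauQuartile), 3))
  d <- simulateOrdinal(spec, 800, seed = 61)
  s1 <- runStage1(d)
  f <- fitDwls(mgModel(3, "measurement"), s1)
  expect_identical(f@df, 0L)
  expect_lt(f@discrepancy, 1e-10)
  expect_lt(f@chisq, 1e-6)
})

test_that("one-factor parameters are recovered from large samples", {
  spec <- makeHadsLikeSpec("one_factor_7")
  d <- simulateOrdinal(spec, 5000, seed = 62)
  s1 <- runStage1(d, design = "single_group")
  f <- fitDwls(mdModel(7), s1)
  lam <- estimates(f)[paste0("lambda.item", 1:7)]
  expect_true(all(abs(lam - spec@loadings[1, ]) < 0.05))
  # thresholds recover the generating cut points (intercepts are zero and
  # the underlying scale has unit variance, so the scales coincide)
  for (i in c(1, 4, 7))
    expect_true(all(abs(thresholds(s1)[[i]] - spec@thresholds[[i]]) < 0.06))
})

test_that("a focal group that copies the reference yields null differences", {
  d <- nullStage1()$data
  resp <- responses(d)[groupLabels(d) == "ref", ]
  dup <- new("OrdinalDataset", responses = rbind(resp, resp),
             group = factor(rep(c("ref", "focal"), each = nrow(resp)),
                            levels = c("ref", "focal")),
             covariates = data.frame(), itemNames = itemNames(d),
             nCategories = 4L)
  s1 <- runStage1(dup)
  expect_true(all(abs(underlyingMeans(s1)[2, ]) < 1e-6))
  f <- fitDwls(mgModel(7, "measurement"), s1)
  # moment values coincide exactly; per-block DWLS weights differ slightly,
  # so per-group estimates agree to weighting precision, not machine precision
  expect_lt(max(abs(estimates(f)[paste0("lambda.ref.item", 1:7)] -
                      estimates(f)[paste0("lambda.foc.item", 1:7)])), 0.01)
  fn <- fitDwls(mgModel(7, "constrained"), s1)
  expect_lt(abs(estimates(fn)["kappa.foc"]), 1e-4)
  expect_lt(abs(estimates(fn)["phi.foc"] - 1), 0.01)
})

test_that("the fit discrepancy is invariant to item reordering", {
  d <- nullStage1()$data
  perm <- c(4, 1, 7, 2, 6, 3, 5)
  dP <- new("OrdinalDataset", responses = responses(d)[, perm],
            group = groupLabels(d), covariates = data.frame(),
            itemNames = itemNames(d)[perm], nCategories = 4L)
  f1 <- fitDwls(mgModel(7, "constrained"), nullStage1()$stage1)
  f2 <- fitDwls(mgModel(7, "constrained",
                        itemNames = itemNames(dP)), runStage1(dP))
  expect_equal(f1@discrepancy, f2@discrepancy, tolerance = 1e-6)
  expect_equal(f1@chisq, f2@chisq, tolerance = 1e-4)
})

test_that("freeing parameters never increases the minimized discrepancy", {
  s1 <- uniformDifStage1()$stage1
  path <- list(mgModel(7, "constrained"),
               mgModel(7, "constrained", freeNu = 3),
               mgModel(7, "constrained", freeNu = 3, freeLambda = 3),
               mgModel(7, "constrained", freeNu = c(1, 3), freeLambda = 3))
  disc <- vapply(path, function(m) fitDwls(m, s1)@discrepancy, numeric(1))
  expect_true(all(diff(disc) <= 1e-8))
})

test_that("the WLS chi-square is calibrated under a correct model", {
  # correctly specified constrained model on no-bias data
  ch <- vapply(1:40, function(r) {
    d <- simulateOrdinal(makeHadsLikeSpec("no_dif"), 500, seed = 600 + r)
    fitDwls(mgModel(7, "constrained"), runStage1(d))@chisq
  }, numeric(1))
  expect_lt(abs(mean(ch) - 40) / 40, 0.10)
})

test_that("misfit grows linearly with the sample size", {
  spec <- makeHadsLikeSpec("uniform_dif")
  ncp <- function(n, seeds) mean(vapply(seeds, function(s) {
    fitDwls(mgModel(7, "constrained"),
            runStage1(simulateOrdinal(spec, n, seed = s)))@chisq - 40
  }, numeric(1)))
  small <- ncp(400, 701:703)
  big <- ncp(1600, 704:706)
  expect_gt(big / small, 2)
  expect_lt(big / small, 8)
})
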