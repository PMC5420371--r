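test_that("the multidimensional models carry the published df pattern", {
  s1 <- mdStage1()$stage1
  meas <- fitMdMeasurement(s1)
  nb <- fitMdNoBias(s1)
  expect_identical(meas@df, 76L)
  expect_identical(nb@df, 100L)
  expect_identical(fitMdNoBias(s1, freeDirect = cbind(4L, 2L))@df, 99L)
})

test_that("the factor correlation and violator associations are recovered", {
  s1 <- mdStage1()$stage1
  nb <- fitMdNoBias(s1)
  expect_lt(abs(estimates(nb)["psi.f1.f2"] - 0.8), 0.05)
  expect_lt(abs(estimates(nb)["cov.f1.age"] + 0.24), 0.07)
  # a binary violator's observed correlation is the latent-layer value
  # attenuated by phi(z)/sqrt(p(1-p)) of the thresholding at prevalence 0.41
  att <- dnorm(qnorm(0.59)) / sqrt(0.41 * 0.59)
  expect_lt(abs(estimates(nb)["cov.f1.gender"] + 0.16 * att), 0.07)
})

test_that("an uncorrelated-factor generator yields a null estimate", {
  spec <- makeHadsLikeSpec("two_factor_14")
  spec@factorCorr <- 0
  spec@violators <- list()
  d <- simulateOrdinal(spec, 2000, seed = 901)
  s1 <- runStage1(d, design = "single_group")
  f <- fitMdMeasurement(s1)
  expect_lt(abs(estimates(f)["psi.f1.f2"]), 0.06)
})

test_that("effect size r is the standardized direct effect", {
  expect_equal(effectSizeR(0.12), 0.12)
  expect_equal(effectSizeR(0, 3, 0.5), 0)
  expect_equal(effectSizeR(0.2, 0.5, 2), 0.05)
  expect_error(effectSizeR(0.1, 0, 1))
})

test_that("injected direct effects are recovered with correct attribution", {
  # a binary violator enters as its 0/1 indicator, so the standardized
  # effect of size 0.4 is 0.4 * sd(V) ~ 0.20
  spec <- makeHadsLikeSpec("two_factor_14")
  spec@difDefs <- data.frame(item = c(4L, 9L), violator = c("age", "gender"),
                             type = "uniform", size = c(0.18, 0.40))
  d <- simulateOrdinal(spec, 2000, seed = 902)
  rep <- runMultidimensionalDif(d, violators = c("gender", "age"))
  f <- findings(rep)
  expect_true(any(f$item == "item4" & f$violator == "age"))
  expect_true(any(f$item == "item9" & f$violator == "gender"))
  got <- f[f$item == "item4" & f$violator == "age", ]
  expect_lt(abs(got$effectSize - 0.18), 0.08)
  got9 <- f[f$item == "item9" & f$violator == "gender", ]
  expect_lt(abs(got9$effectSize - 0.4 * sqrt(0.41 * 0.59)), 0.08)
  # df drops by one per accepted finding
  final <- modelTrail(rep)[["Final Model"]]
  expect_identical(final@df, 100L - nrow(f))
})

test_that("reported associations are invariant to rescaling the violator", {
  spec <- makeHadsLikeSpec("two_factor_14")
  spec@difDefs <- data.frame(item = 4L, violator = "age", type = "uniform",
                             size = 0.2)
  d <- simulateOrdinal(spec, 1200, seed = 903)
  cv <- covariates(d)
  cv$age <- (cv$age - 50) / 18          # years -> z-scores
  d2 <- new("OrdinalDataset", responses = responses(d), group = NULL,
            covariates = cv, itemNames = itemNames(d), nCategories = 4L)
  r1 <- runMultidimensionalDif(d, violators = c("gender", "age"))
  r2 <- runMultidimensionalDif(d2, violators = c("gender", "age"))
  expect_identical(findings(r1)$item, findings(r2)$item)
  expect_equal(findings(r1)$effectSize, findings(r2)$effectSize,
               tolerance = 1e-6)
  a1 <- associations(r1); a2 <- associations(r2)
  expect_equal(a1$r, a2$r, tolerance = 1e-6)
  expect_true(all(abs(a1$r) <= 1))
})

test_that("bias absorption: contaminated items fake a violator association", {
  # no true age association; a minority of the factor's items carry
  # mixed-sign age bias (the identifiable configuration)
  spec <- makeHadsLikeSpec("two_factor_14")
  spec@violators[[2]]$corFactors <- c(0, 0)
  spec@difDefs <- data.frame(item = c(8L, 10L, 14L), violator = "age",
                             type = "uniform", size = c(0.15, -0.25, -0.20))
  d <- simulateOrdinal(spec, 2000, seed = 904)
  rep <- runMultidimensionalDif(d, violators = c("gender", "age"))
  f <- findings(rep)
  expect_true(all(c("item8", "item10", "item14") %in% f$item))
  a <- associations(rep)
  unadj <- a[a$context == "unadjusted" & a$varA == "f2" & a$varB == "age", ]
  adj <- a[a$context == "adjusted" & a$varA == "f2" & a$varB == "age", ]
  expect_lt(unadj$r, adj$r - 0.03)      # net-negative bias leaks into r
  expect_true(abs(adj$r) < 2 * adj$se + 0.02)  # adjusted: compatible with 0
})

test_that("multigroup and multidimensional routes agree on uniform bias", {
  agree <- vapply(1:4, function(r) {
    d <- simulateOrdinal(makeHadsLikeSpec("uniform_dif"), 2000,
                         seed = 910 + r)
    mg <- runMultigroupDif(d)
    # same data through the single-group route, group as a binary violator
    dMd <- new("OrdinalDataset", responses = responses(d), group = NULL,
               covariates = data.frame(group = as.numeric(
                 groupLabels(d) == "focal")),
               itemNames = itemNames(d), nCategories = 4L)
    md <- runMultidimensionalDif(dMd, violators = "group",
                                 itemFactor = rep(1L, 7))
    mgItems <- sort(unique(findings(mg)$item[findings(mg)$type == "uniform"]))
    mdItems <- sort(unique(findings(md)$item))
    identical(mgItems, mdItems)
  }, logical(1))
  expect_gte(mean(agree), 0.75)
})
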