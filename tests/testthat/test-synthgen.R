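test_that("scenario specs have the promised structure", {
  s7 <- makeHadsLikeSpec("one_factor_7")
  expect_s4_class(s7, "GeneratorSpec")
  expect_identical(s7@nItems, 7L)
  expect_true(all(lengths(s7@thresholds) == 3L))

  s0 <- makeHadsLikeSpec("no_dif")
  expect_identical(nrow(s0@difDefs), 0L)
  expect_identical(s0@nGroups, 2L)

  su <- makeHadsLikeSpec("uniform_dif", difItem = 3L, difSize = 0.5)
  expect_identical(su@difDefs,
                   data.frame(item = 3L, violator = "group",
                              type = "uniform", size = 0.5))

  s14 <- makeHadsLikeSpec("two_factor_14")
  expect_identical(s14@factorCorr, 0.8)
  expect_identical(max(s14@itemFactor), 2L)

  expect_error(makeHadsLikeSpec("seven_items"), "valid scenarios")
})

test_that("spec invariants are enforced", {
  s <- makeHadsLikeSpec("one_factor_7")
  s@thresholds[[2]] <- c(0.5, 0.5, 1)        # not strictly increasing
  expect_error(validObject(s), "increasing")
  s <- makeHadsLikeSpec("one_factor_7")
  s@residualSds[1] <- -1
  expect_error(validObject(s), "residualSds")
  s <- makeHadsLikeSpec("no_dif")
  s@difDefs <- data.frame(item = 9L, violator = "group",
                          type = "uniform", size = 0.2)
  expect_error(validObject(s), "nonexistent items")
})

test_that("simulation is deterministic and conserves counts", {
  spec <- makeHadsLikeSpec("no_dif")
  d1 <- simulateOrdinal(spec, 150, seed = 7)
  d2 <- simulateOrdinal(spec, 150, seed = 7)
  expect_identical(responses(d1), responses(d2))
  expect_false(identical(responses(d1),
                         responses(simulateOrdinal(spec, 150, seed = 8))))
  counts <- apply(responses(d1) + 1L, 2, tabulate, nbins = 4)
  expect_true(all(colSums(counts) == 300))
  expect_error(simulateOrdinal(spec, 0, seed = 1), "nPerGroup")
})

test_that("with zero loadings the category margins follow the thresholds", {
  spec <- makeGeneratorSpec(3L, loadings = 0, residualSds = rep(1, 3),
                            thresholds = rep(list(tauQuartile), 3))
  d <- simulateOrdinal(spec, 1e5, seed = 9)
  freq <- prop.table(table(responses(d)[, 2]))
  expect_true(all(abs(freq - 0.25) < 0.01))
})

test_that("injected uniform bias shifts the focal latent mean by its size", {
  spec <- makeHadsLikeSpec("uniform_dif", difItem = 3L, difSize = 0.5,
                           groupMeanDiff = 0)
  sim <- simulateOrdinal(spec, 20000, seed = 10, returnLatent = TRUE)
  foc <- groupLabels(sim$data) == "focal"
  shift <- colMeans(sim$latent[foc, ]) - colMeans(sim$latent[!foc, ])
  expect_equal(unname(shift[3]), 0.5, tolerance = 0.03)
  expect_lt(max(abs(shift[-3])), 0.03)
})

test_that("nonuniform bias scales with the factor score", {
  spec <- makeHadsLikeSpec("nonuniform_dif", difItem = 3L, difSize = 0.3,
                           groupMeanDiff = 0)
  sim <- simulateOrdinal(spec, 20000, seed = 11, returnLatent = TRUE)
  foc <- groupLabels(sim$data) == "focal"
  # regression of the item's latent response on the factor score: slope
  # difference across groups equals the injected loading increment
  bFoc <- stats::coef(stats::lm(sim$latent[foc, 3] ~ sim$factors[foc, 1]))[2]
  bRef <- stats::coef(stats::lm(sim$latent[!foc, 3] ~ sim$factors[!foc, 1]))[2]
  expect_equal(unname(bFoc - bRef), 0.3, tolerance = 0.03)
})

test_that("equal-parameter groups differ only by sampling error", {
  spec <- makeHadsLikeSpec("no_dif")
  reject <- vapply(1:100, function(r) {
    d <- simulateOrdinal(spec, 300, seed = 500 + r)
    tab <- table(responses(d)[, 1 + (r %% 7)], groupLabels(d))
    suppressWarnings(stats::chisq.test(tab)$p.value) < 0.01
  }, logical(1))
  expect_gte(mean(!reject), 0.95)
})

test_that("the reference group survives a CSV round trip", {
  d <- simulateOrdinal(makeHadsLikeSpec("no_dif"), 40, seed = 13)
  path <- tempfile(fileext = ".csv")
  writeOrdinalData(d, path)
  d2 <- readOrdinalData(path, items = itemNames(d), group = "group")
  # reference = first level in the file, not alphabetical order
  expect_identical(levels(groupLabels(d2)), c("ref", "focal"))
})

test_that("datasets round-trip through CSV", {
  spec <- makeHadsLikeSpec("two_factor_14")
  d <- simulateOrdinal(spec, 120, seed = 12)
  path <- tempfile(fileext = ".csv")
  writeOrdinalData(d, path)
  d2 <- readOrdinalData(path, items = itemNames(d),
                        covariateNames = c("gender", "age"))
  expect_identical(unname(responses(d2)), unname(responses(d)))
  expect_equal(covariates(d2)$age, covariates(d)$age, tolerance = 1e-8)

  yml <- tempfile(fileext = ".yaml")
  writeGeneratorSpec(spec, yml)
  obj <- yaml::read_yaml(yml)
  expect_identical(obj$nItems, 14L)
  expect_identical(obj$factorCorr, 0.8)
})
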