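test_that("pooled thresholds are the probit of pooled cumulative proportions", {
  s1 <- nullStage1()$stage1
  d <- nullStage1()$data
  # reproduce by hand: pooled probit, rescaled so the reference group is
  # standardized against the shared thresholds
  x <- responses(d)[, 4]
  tauPooled <- qnorm(cumsum(tabulate(x + 1, 4) / length(x))[-4])
  tau <- thresholds(s1)[[4]]
  # the reported thresholds are an affine transform of the pooled probit
  fitAff <- stats::lm(tau ~ tauPooled)
  expect_lt(max(abs(stats::resid(fitAff))), 1e-8)
})

test_that("no-bias two-group data give near-standard focal moments", {
  s1 <- nullStage1()$stage1
  expect_true(all(abs(underlyingMeans(s1)[2, ]) < 0.08))
  expect_true(all(abs(underlyingSds(s1)[2, ] - 1) < 0.08))
  # reference group is standardized by construction
  expect_identical(unname(underlyingMeans(s1)[1, ]), rep(0, 7))
  expect_identical(unname(underlyingSds(s1)[1, ]), rep(1, 7))
})

test_that("a latent focal shift moves focal item means by loading times shift", {
  spec <- makeHadsLikeSpec("no_dif")
  spec@factorMeans <- matrix(c(0, 0.5), 2, 1)
  d <- simulateOrdinal(spec, 2000, seed = 51)
  s1 <- runStage1(d)
  lam <- spec@loadings[1, ]
  expect_true(all(abs(underlyingMeans(s1)[2, ] - 0.5 * lam) < 0.08))
})

test_that("single-group design standardizes all underlying variables", {
  s1 <- mdStage1()$stage1
  expect_identical(unname(underlyingMeans(s1)), matrix(0, 1, 14))
  expect_identical(unname(underlyingSds(s1)), matrix(1, 1, 14))
  R <- correlations(s1)[[1]]
  expect_identical(dim(R), c(16L, 16L))
  expect_equal(unname(diag(R)), rep(1, 16))
  expect_true(all(abs(R) <= 1))
})

test_that("multigroup design requires a group label", {
  d <- simulateOrdinal(makeHadsLikeSpec("one_factor_7"), 100, seed = 52)
  expect_error(runStage1(d, design = "multigroup"), "group")
})

test_that("the asymptotic covariance is symmetric with positive diagonal", {
  for (s1 in list(nullStage1()$stage1, mdStage1()$stage1)) {
    G <- s1@acov
    expect_lt(max(abs(G - t(G))), 1e-10)
    expect_true(all(diag(G) > 0))
    expect_identical(dim(G), rep(length(s1@moments), 2L))
  }
})

test_that("influence-function acov agrees with the bootstrap oracle", {
  d <- simulateOrdinal(makeHadsLikeSpec("no_dif"), 400, seed = 53)
  s1 <- runStage1(d)
  s1b <- runStage1(d, acovMethod = "bootstrap", B = 150, seed = 54)
  ratio <- diag(s1@acov) / diag(s1b@acov)
  expect_gt(median(ratio), 0.75)
  expect_lt(median(ratio), 1.35)
  expect_gt(cor(diag(s1@acov), diag(s1b@acov)), 0.9)
})

test_that("listwise deletion drops incomplete respondents with a message", {
  d <- nullStage1()$data
  resp <- responses(d)
  resp[c(3, 10), 2] <- NA
  d2 <- new("OrdinalDataset", responses = resp, group = groupLabels(d),
            covariates = covariates(d), itemNames = itemNames(d),
            nCategories = 4L)
  expect_message(s1 <- runStage1(d2), "2 incomplete")
  expect_identical(sum(s1@nPerGroup), nrow(resp) - 2L)
})

test_that("non-normal pairs are flagged but the run continues", {
  # a dependence that reverses sign across the scale cannot come from any
  # bivariate normal, whatever the thresholds
  set.seed(55)
  n <- 4000
  y1 <- rnorm(n)
  y2 <- ifelse(abs(y1) > 0.8, y1, -y1) + 0.3 * rnorm(n)
  resp <- cbind(findInterval(y1, tauQuartile),
                findInterval(y2 / sd(y2), tauQuartile),
                findInterval(rnorm(n), tauQuartile))
  colnames(resp) <- paste0("it", 1:3)
  d <- new("OrdinalDataset", responses = resp, group = NULL,
           covariates = data.frame(), itemNames = colnames(resp),
           nCategories = 4L)
  s1 <- runStage1(d, design = "single_group")
  expect_gte(nrow(flaggedPairs(s1)), 1L)
  expect_true(any(flaggedPairs(s1)[, 1] == "it1" &
                    flaggedPairs(s1)[, 2] == "it2"))
})
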