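# thresholds -----------------------------------------------------------------

test_that("thresholds are the probit of cumulative proportions", {
  expect_equal(as.numeric(estimateThresholds(c(250, 250, 250, 250))),
               qnorm(c(0.25, 0.5, 0.75)), tolerance = 1e-6)
  expect_equal(as.numeric(estimateThresholds(c(100, 200, 300, 400))),
               qnorm(c(0.1, 0.3, 0.6)), tolerance = 1e-6)
})

test_that("boundary handling collapses and pseudo-counts as documented", {
  # empty extremes collapse away
  tau <- estimateThresholds(c(0, 500, 500, 0))
  expect_equal(as.numeric(tau), 0)
  expect_identical(attr(tau, "map"), c(1L, 1L, 2L, 2L))
  # interior empties get a 0.5 pseudo-count, keeping thresholds distinct
  tau2 <- estimateThresholds(c(300, 0, 700))
  expect_identical(length(as.numeric(tau2)), 2L)
  expect_true(all(diff(as.numeric(tau2)) > 0))
  expect_error(estimateThresholds(c(0, 800, 0, 0), item = "itemX"), "itemX")
})

# polychoric correlation ------------------------------------------------------

test_that("independence and perfect concordance are recovered exactly", {
  tab <- exactTable(0.5, tauQuartile, tauQuartile)
  indep <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_lt(abs(estimatePolychoric(indep, tauQuartile, tauQuartile)$rho), 1e-3)

  conc <- diag(c(100, 200, 300, 150))
  fit <- suppressWarnings(estimatePolychoric(conc, tauQuartile, tauQuartile))
  expect_equal(fit$rho, 0.999)
  expect_true(fit$boundary)
})

test_that("estimates on exact-probability tables hit the generating rho", {
  for (rho in c(-0.7, 0.2, 0.5)) {
    tab <- exactTable(rho, tauQuartile, tauQuartile)
    expect_equal(estimatePolychoric(tab, tauQuartile, tauQuartile)$rho, rho,
                 tolerance = 2e-3)
  }
})

test_that("production estimator matches the grid-search likelihood argmax", {
  set.seed(301)
  for (r in 1:12) {
    rho <- runif(1, -0.9, 0.9)
    tA <- sort(runif(3, -1.2, 1.2))
    tB <- sort(runif(3, -1.2, 1.2))
    tab <- matrix(stats::rmultinom(1, 800,
                                   semdif:::.cellProbs(rho, tA, tB)), 4, 4)
    got <- estimatePolychoric(tab, tA, tB)$rho
    want <- gridPolychoric(tab, tA, tB)
    expect_lt(abs(got - want), 1e-3)
  }
})

test_that("the estimate is invariant to transposing the table", {
  set.seed(302)
  tA <- c(-0.8, 0, 0.9); tB <- c(-0.5, 0.3, 1.1)
  tab <- matrix(stats::rmultinom(1, 1500,
                                 semdif:::.cellProbs(0.45, tA, tB)), 4, 4)
  expect_equal(estimatePolychoric(tab, tA, tB)$rho,
               estimatePolychoric(t(tab), tB, tA)$rho, tolerance = 1e-6)
})

# polyserial correlation ------------------------------------------------------

test_that("polyserial estimates track the latent correlation", {
  set.seed(303)
  n <- 40000
  y <- rnorm(n)
  v <- 0.6 * y + sqrt(1 - 0.36) * rnorm(n)
  x <- findInterval(y, tauQuartile)
  expect_equal(polyserialCorrelation(x, v)$rho, 0.6, tolerance = 0.02)
  # shuffling the pairing destroys the association
  expect_lt(abs(polyserialCorrelation(x, sample(v))$rho), 0.02)
  # a binary covariate without latent shift is uncorrelated
  g <- rbinom(n, 1, 0.4)
  expect_lt(abs(polyserialCorrelation(findInterval(rnorm(n), tauQuartile),
                                      g)$rho), 0.02)
  expect_error(polyserialCorrelation(x, rep(1, n)), "constant")
})

# bivariate normality screen --------------------------------------------------

test_that("the RMSEA diagnostic is zero at perfect and at chance-level fit", {
  tab <- exactTable(0.4, tauQuartile, tauQuartile, n = 1000)
  d <- bivariateNormalityRmsea(tab, 0.4, tauQuartile, tauQuartile)
  expect_equal(d$chisq, 0, tolerance = 1e-6)
  expect_equal(d$rmsea, 0)
  expect_identical(d$df, 14L)  # 4x4 cells - 1 - 1 fitted correlation
  expect_false(d$flag)
})

test_that("tail-dependent latent data raise the diagnostic above normal data", {
  set.seed(304)
  reps <- 40
  rmseaT <- rmseaN <- numeric(reps)
  for (r in 1:reps) {
    n <- 3000
    # t(3)-copula style latent pair: strong tail dependence, same correlation
    W <- sqrt(3 / stats::rchisq(n, df = 3))
    Z <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, 0.5, 0.5, 1), 2))
    Xt <- Z * W
    Xn <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, 0.5, 0.5, 1), 2))
    for (kind in c("t", "n")) {
      X <- if (kind == "t") Xt else Xn
      k1 <- findInterval(X[, 1] / sd(X[, 1]), tauQuartile)
      k2 <- findInterval(X[, 2] / sd(X[, 2]), tauQuartile)
      tab <- table(factor(k1, levels = 0:3), factor(k2, levels = 0:3))
      f <- suppressWarnings(estimatePolychoric(tab, tauQuartile, tauQuartile))
      d <- bivariateNormalityRmsea(tab, f$rho, tauQuartile, tauQuartile)
      if (kind == "t") rmseaT[r] <- d$rmsea else rmseaN[r] <- d$rmsea
    }
  }
  expect_gt(mean(rmseaT), mean(rmseaN))
  expect_gt(mean(rmseaT > 0.1), 0.5)   # the screen catches gross violations
  expect_lt(mean(rmseaN > 0.1), 0.1)
})
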