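# Shared fixtures, built once per test run and cached.  Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# quartile thresholds used in several closed-form checks
tauQuartile <- qnorm(c(0.25, 0.5, 0.75))

# a two-group no-bias dataset and its Stage 1 result
nullStage1 <- function() fixture("nullStage1", function() {
  d <- simulateOrdinal(makeHadsLikeSpec("no_dif"), 2000, seed = 42)
  list(data = d, stage1 = runStage1(d))
})

# a two-group dataset with one injected uniform bias (item 3, size 0.5)
uniformDifStage1 <- function() fixture("uniformDifStage1", function() {
  d <- simulateOrdinal(makeHadsLikeSpec("uniform_dif"), 1000, seed = 43)
  list(data = d, stage1 = runStage1(d))
})

# a single-group two-factor dataset with violators and its Stage 1 result
mdStage1 <- function() fixture("mdStage1", function() {
  d <- simulateOrdinal(makeHadsLikeSpec("two_factor_14"), 2000, seed = 44)
  list(data = d,
       stage1 = runStage1(d, design = "single_group",
                          covariateNames = c("gender", "age")))
})

# contingency table with expected counts of an exact bivariate normal
exactTable <- function(rho, tauRow, tauCol, n = 1e6) {
  n * semdif:::.cellProbs(rho, tauRow, tauCol)
}

# brute-force polychoric oracle: grid search over the same likelihood,
# vectorized across the whole grid in one CDF call
gridPolychoric <- function(tab, tauRow, tauCol,
                           grid = seq(-0.99, 0.99, by = 0.001)) {
  a <- c(-Inf, tauRow, Inf)
  b <- c(-Inf, tauCol, Inf)
  na <- length(a); nb <- length(b); ng <- length(grid)
  corner <- expand.grid(a = a, b = b)
  P <- array(pbvnorm(rep(corner$a, times = ng), rep(corner$b, times = ng),
                     rep(grid, each = na * nb)), dim = c(na, nb, ng))
  pr <- P[-1, -1, , drop = FALSE] - P[-na, -1, , drop = FALSE] -
    P[-1, -nb, , drop = FALSE] + P[-na, -nb, , drop = FALSE]
  ll <- colSums(log(pmax(matrix(pr, (na - 1) * (nb - 1), ng), 1e-12)) *
                  as.vector(tab))
  grid[which.max(ll)]
}
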