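test_that("transition matrix has the documented rows and handles multi-year gaps", {
  M <- transitionMatrix(1, 0, 0)
  expect_equal(M["A", "A"], 1)
  expect_equal(M["O", "A"], 1) # forced return when gamma' = 0

  M0 <- transitionMatrix(0, 0.3, 0.6)
  expect_equal(unname(M0[, "D"]), c(1, 1, 1)) # death absorbs everything

  M1 <- transitionMatrix(0.78, 0.2, 0.2)
  M3 <- transitionMatrix(0.78, 0.2, 0.2, dt = 3)
  expect_equal(M3, M1 %*% M1 %*% M1)
  expect_error(transitionMatrix(0.5, 0.2, 0.2, dt = 0), "positive")
})

test_that("transition matrices are row-stochastic with absorbing death for any parameters", {
  set.seed(42)
  for (i in 1:25) {
    M <- transitionMatrix(runif(1), runif(1), runif(1), dt = sample(1:4, 1))
    expect_equal(unname(rowSums(M)), c(1, 1, 1))
    expect_equal(unname(M["D", ]), c(0, 0, 1))
  }
})

test_that("emission probabilities follow the closed-capture product and state zeros", {
  expect_equal(emissionProb(c(1, 0), "A", 0.36), 0.36 * 0.64)
  expect_equal(emissionProb(c(0, 0, 0), "O", 0.9), 1)
  expect_equal(emissionProb(c(1, 0), "D", 0.36), 0)
  expect_equal(emissionProb(c(0, 0), "O", 0.5), 1)
})

test_that("single- and two-primary histories have closed-form likelihoods", {
  # T = 1: conditional M0 term
  ll <- historyLoglik(
    counts = 2L, K = 3L, phi = numeric(0), gammaDP = numeric(0),
    gammaP = numeric(0), p = 0.4, dt = integer(0)
  )
  expect_equal(ll, log(0.4^2 * 0.6 / (1 - 0.6^3)))

  # T = 2, phi = 1, gamma'' = 0: the second primary is a plain binomial product
  ll2 <- historyLoglik(
    counts = c(1L, 1L), K = c(2L, 2L), phi = 1, gammaDP = 0,
    gammaP = 0, p = c(0.3, 0.5)
  )
  expect_equal(ll2, log(0.3 * 0.7 / (1 - 0.7^2)) + log(0.5 * 0.5))
})

test_that("history probabilities match independent state-path enumeration", {
  set.seed(14)
  K <- c(2L, 3L, 2L)
  for (i in 1:10) {
    phi <- runif(2, 0.4, 0.95)
    gdp <- runif(2, 0, 0.5)
    gp <- runif(2, 0, 0.9)
    p <- runif(3, 0.1, 0.8)
    dt <- sample(1:3, 2, replace = TRUE)
    counts <- c(sample(1:2, 1), sample(0:3, 1), sample(0:2, 1))
    got <- exp(historyLoglik(counts, K, phi, gdp, gp, p, dt))
    want <- statePathProb(counts, K, phi, gdp, gp, p, dt)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("probabilities over all post-first-capture histories sum to one", {
  set.seed(3)
  K <- c(2L, 2L, 2L)
  for (i in 1:12) {
    phi <- runif(2, 0.3, 0.99)
    gdp <- runif(2, 0, 0.6)
    gp <- runif(2, 0, 0.9)
    p <- runif(3, 0.05, 0.9)
    for (f in 1:3) {
      expect_equal(enumHistorySum(K, phi, gdp, gp, p, f), 1, tolerance = 1e-10)
    }
  }
})

test_that("the vectorised objective agrees with per-history sums and is additive", {
  d <- tinyDesign(2002:2004, K = 2L)
  st <- modelStructure(phi = "sex", gammaMode = "markovian", p = "sex")
  sec <- rbind(
    c(1L, 0L, 0L, 0L, 1L, 1L),
    c(0L, 1L, 1L, 0L, 0L, 0L),
    c(0L, 0L, 1L, 1L, 0L, 1L),
    c(1L, 1L, 0L, 0L, 0L, 0L),
    c(0L, 0L, 0L, 1L, 0L, 0L)
  )
  sexes <- c("male", "female", "male", "female", "male")
  ch <- chFromSec(sec, sexes, d)
  beta <- qlogis(c(0.8, 0.75, 0.2, 0.3, 0.35, 0.15))
  names(beta) <- parameterNames(st, d)

  # dual route: scalar reference implementation summed by hand
  pm <- camtrapRD:::.buildParMap(st, d)
  rp <- camtrapRD:::.realParams(beta, pm)
  D <- detectionCounts(ch)
  want <- 0
  for (i in seq_len(nrow(D))) {
    s <- if (sexes[i] == "male") 1L else 2L
    want <- want - historyLoglik(
      D[i, ], secondaryCounts(d), rp$phi[s, ], rp$gdp, rp$gp, rp$p[s, ],
      camtrapRD:::.buildParMap(st, d)$dt
    )
  }
  expect_equal(negLoglik(beta, st, ch), unname(want), tolerance = 1e-12)

  # doubling every individual doubles the objective
  ch2 <- chFromSec(rbind(sec, sec), c(sexes, sexes), d)
  expect_equal(negLoglik(beta, st, ch2), 2 * negLoglik(beta, st, ch), tolerance = 1e-12)

  # empty data give a zero objective
  chEmpty <- chFromSec(matrix(integer(0), 0, 6), character(0), d)
  expect_equal(negLoglik(beta, st, chEmpty), 0)
})

test_that("a Markovian model at gamma' = gamma'' reproduces the random-model likelihood", {
  d <- tinyDesign(2002:2005, K = 3L)
  sec <- matrix(rbinom(8 * 12, 1, 0.4), 8)
  sec[rowSums(sec) == 0, 1] <- 1L
  ch <- chFromSec(sec, rep(c("male", "female"), 4), d)

  stR <- modelStructure(phi = ".", gammaMode = "random", p = ".")
  stM <- modelStructure(phi = ".", gammaMode = "markovian", p = ".")
  betaR <- qlogis(c(0.8, 0.25, 0.4))
  names(betaR) <- parameterNames(stR, d)
  betaM <- qlogis(c(0.8, 0.25, 0.25, 0.4))
  names(betaM) <- parameterNames(stM, d)
  expect_equal(negLoglik(betaR, stR, ch), negLoglik(betaM, stM, ch), tolerance = 1e-12)
})

test_that("with no emigration the phi profile matches a CJS likelihood up to a constant", {
  set.seed(8)
  cfg <- smallSimConfig(gammaDP = 0, recruitRate = 0.15)
  sim <- simulatePopulation(cfg, seed = 31)
  ch <- buildCaptureHistories(filterIndependent(sim$events), cfg$design)
  st <- modelStructure(phi = ".", gammaMode = "none", p = ".")
  pm <- camtrapRD:::.buildParMap(st, ch@design)
  p0 <- 0.3
  K <- secondaryCounts(ch@design)
  pstar <- 1 - (1 - p0)^K
  presence <- (detectionCounts(ch) > 0) * 1L

  pkg <- function(phi) {
    beta <- numeric(pm$npar)
    beta[grepl("^p", pm$parNames)] <- qlogis(p0)
    beta[grepl("^phi", pm$parNames)] <- qlogis(phi)
    names(beta) <- pm$parNames
    -negLoglik(beta, st, ch)
  }
  cjs <- function(phi) cjsLoglik(presence, rep(phi, ncol(presence) - 1), pstar)
  grid <- seq(0.55, 0.95, by = 0.01)
  diffs <- vapply(grid, pkg, numeric(1)) - vapply(grid, cjs, numeric(1))
  expect_lt(sd(diffs), 1e-8) # identical shape in phi
  expect_equal(
    optimize(function(x) -pkg(x), c(0.3, 0.99), tol = 1e-9)$minimum,
    optimize(function(x) -cjs(x), c(0.3, 0.99), tol = 1e-9)$minimum,
    tolerance = 1e-5
  )
})
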