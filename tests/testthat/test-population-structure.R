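jaguarYears <- c(2002:2008, 2011:2015)

yearMatrix <- function(rows) {
  m <- matrix(0L, length(rows), length(jaguarYears),
    dimnames = list(names(rows), jaguarYears)
  )
  for (i in seq_along(rows)) m[i, as.character(rows[[i]])] <- 1L
  m
}

test_that("residency follows the three-consecutive-year rule with gap bridging", {
  m <- yearMatrix(list(
    res = 2003:2005,
    gappy = c(2003, 2005, 2007),
    bridged = c(2008, 2011, 2012),
    buffered = c(2002, 2003, 2004)
  ))
  r <- classifyResidency(m, window = 2003:2007)
  status <- setNames(r$status, r$id)
  expect_equal(status[["res"]], "resident")
  expect_equal(status[["gappy"]], "transient")
  expect_false("bridged" %in% r$id) # never detected inside the window
  # detections in the 2002 buffer year extend the run
  expect_equal(status[["buffered"]], "resident")

  # the unsurveyed 2009-2010 years do not break a run
  r2 <- classifyResidency(yearMatrix(list(b = c(2008, 2011, 2012))),
    window = 2008:2012
  )
  expect_equal(r2$status, "resident")

  expect_error(classifyResidency(m, window = 1999:2003), "not all covered")
})

test_that("residency classification equals a brute-force run-length oracle", {
  set.seed(23)
  years <- 2002:2008
  for (rep in 1:5) {
    m <- matrix(rbinom(30 * 7, 1, 0.4), 30, dimnames = list(sprintf("i%02d", 1:30), years))
    m[rowSums(m[, 2:6]) == 0, 4] <- 1L
    r <- classifyResidency(m, window = 2003:2007, buffer = 1)
    for (i in seq_len(nrow(r))) {
      v <- m[r$id[i], as.character(2002:2008)]
      expect_equal(r$longestRun[i], runLengthOracle(v))
      expect_equal(r$status[i], if (runLengthOracle(v) >= 3) "resident" else "transient")
    }
  }
})

test_that("adding a detected year never demotes a resident", {
  set.seed(31)
  years <- 2002:2008
  for (rep in 1:20) {
    v <- rbinom(7, 1, 0.4)
    v[4] <- 1L
    m <- matrix(v, 1, dimnames = list("x", years))
    base <- classifyResidency(m, window = 2003:2007)$status
    j <- sample(which(v == 0), 1)
    if (is.na(j) || !length(j)) next
    v2 <- v
    v2[j] <- 1L
    m2 <- matrix(v2, 1, dimnames = list("x", years))
    more <- classifyResidency(m2, window = 2003:2007)$status
    if (base == "resident") expect_equal(more, "resident")
  }
})

test_that("permutation test: degenerate cases, invariances, extreme groups", {
  same <- permutationTest(c(3, 4, 5), c(3, 4, 5), nPerm = 999, seed = 1)
  expect_gt(same$p, 0.5)
  expect_equal(permutationTest(c(2, 2), c(2, 2), nPerm = 999)$p, 1)

  ext <- permutationTest(c(0, 0, 0), c(10, 10, 10), nPerm = 999, seed = 1)
  expect_gte(ext$p, 1 / 1000) # minimum attainable Monte-Carlo p
  expect_lte(ext$p, 0.1 + 0.05) # exact enumeration: 2 of 20 splits tie the observed

  a <- c(1.2, 3.4, 2.2, 5.1)
  b <- c(4.0, 6.5, 5.5)
  p1 <- permutationTest(a, b, nPerm = 4999, seed = 7)$p
  p2 <- permutationTest(b, a, nPerm = 4999, seed = 7)$p
  p3 <- permutationTest(10 + 2 * a, 10 + 2 * b, nPerm = 4999, seed = 7)$p
  expect_equal(p1, p3) # affine invariance is exact at a fixed seed
  expect_lt(abs(p1 - p2), 0.03) # relabelling differs only by Monte-Carlo noise
  expect_error(permutationTest(a, b, nPerm = 99), "999")
  expect_error(permutationTest(numeric(0), b), "non-empty")
})

test_that("permutation p-values are uniform under the null", {
  set.seed(17)
  pvals <- replicate(300, {
    permutationTest(rnorm(8), rnorm(8), nPerm = 999)$p
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("paired Wilcoxon matches rank identities and exact enumeration", {
  x <- c(5, 7, 3, 9, 4, 6, 8, 10, 2, 11)
  expect_equal(pairedWilcoxon(x, x), list(V = 0, p = 1, n = 0L, exact = TRUE))

  y <- x - seq(0.1, 1, by = 0.1) # x strictly greater, no ties
  pw <- pairedWilcoxon(x, y)
  expect_equal(pw$V, 55) # n(n+1)/2 with every rank positive
  expect_equal(pw$n, 10L)

  # six pairs, one negative difference of smallest magnitude
  a <- c(10, 12, 14, 16, 18, 20)
  b <- c(10.5, 10, 11, 12, 13, 14)
  got <- pairedWilcoxon(a, b)
  want <- signedRankExact(a - b)
  expect_equal(got$V, want$V)
  expect_equal(got$p, want$p, tolerance = 1e-12)

  # V(x, y) + V(y, x) = n(n+1)/2 without zeros or ties
  expect_equal(pairedWilcoxon(x, y)$V + pairedWilcoxon(y, x)$V, 55)
})

test_that("Mann-Whitney matches exact enumeration for small samples", {
  expect_equal(mannWhitney(1, 1)$p, 1)

  sep <- mannWhitney(c(7, 8, 9), c(1, 2, 3))
  expect_equal(sep$W, 9) # maximal U for n = m = 3
  expect_equal(sep$p, 0.1) # 2 / choose(6, 3)

  set.seed(9)
  for (i in 1:5) {
    x <- round(rnorm(4, 0, 5), 3)
    y <- round(rnorm(5, 1, 5), 3)
    got <- mannWhitney(x, y)
    want <- rankSumExact(x, y)
    expect_equal(got$W, want$W)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("span regression recovers forced geometries and generated slopes", {
  yrs <- c(3, 5, 7, 4, 6, 8)
  sexes <- rep(c("male", "female"), each = 3)
  # consecutive detection: span = years - 1
  r1 <- suppressWarnings(detectionSpanRegression(yrs - 1, yrs, sexes))
  expect_equal(r1$bySex$slope, c(1, 1), tolerance = 1e-10)
  expect_equal(r1$bySex$intercept, c(-1, -1), tolerance = 1e-10)
  # every-other-year detection: span = 2 * years - 2
  r2 <- suppressWarnings(detectionSpanRegression(2 * yrs - 2, yrs, sexes))
  expect_equal(r2$bySex$slope, c(2, 2), tolerance = 1e-10)
  expect_equal(r2$slopeDifference$estimate, 0, tolerance = 1e-10)

  set.seed(20)
  n <- 200
  x <- sample(1:8, n, replace = TRUE)
  span <- 1.2 * x - 0.2 + rnorm(n, 0, 0.6)
  r3 <- detectionSpanRegression(span, x, rep("male", n))
  se <- 0.6 / sqrt(sum((x - mean(x))^2))
  expect_lt(abs(r3$bySex$slope - 1.2), 4 * se)

  expect_error(detectionSpanRegression(1:2, 1:2, c("male", "female")), ">= 3")
})

test_that("quarterly subsampling counts each individual once per quarter", {
  mk <- function(id, sex, days) eventsDF(rep(id, length(days)), sex, "S01", days * 24, origin = "2013-02-01 00:00:00")
  ev <- rbind(
    mk("m1", "male", c(10, 100, 200, 300)), # all four quarters
    mk("m2", "male", c(5, 6, 7)), # first quarter only, three events
    mk("f1", "female", 95),
    mk("f2", "female", c(20, 290))
  )
  q <- quarterlySubsample(ev, start = as.Date("2013-02-01"))
  male <- q[q$sex == "male", ]
  expect_equal(male$nDetected, c(2L, 1L, 1L, 1L))
  expect_equal(male$nTotal, rep(2L, 4))
  female <- q[q$sex == "female", ]
  expect_equal(female$nDetected, c(1L, 1L, 0L, 1L))
  expect_true(all(q$proportion <= 1))
  # every detected individual appears in at least one quarter
  expect_equal(sum(tapply(q$nDetected, q$sex, max) > 0), 2L)
  # 5 of 12 detected rounds to the published convention
  expect_equal(round(100 * 5 / 12), 42)
})

test_that("simulated full-year quarterly proportions equal a ledger recount", {
  set.seed(2)
  days <- sort(runif(120, 0, 364))
  ids <- sample(sprintf("m%02d", 1:20), 120, replace = TRUE)
  ev <- eventsDF(ids, "male", "S01", days * 24, origin = "2013-01-01 00:00:00")
  q <- quarterlySubsample(ev, start = as.Date("2013-01-01"))
  bounds <- seq(as.Date("2013-01-01"), by = "3 months", length.out = 5)
  for (k in 1:4) {
    inQ <- as.Date(ev$timestamp) >= bounds[k] & as.Date(ev$timestamp) < bounds[k + 1]
    expect_equal(
      q$nDetected[q$quarter == k & q$sex == "male"],
      length(unique(ev$individual_id[inQ]))
    )
  }
})
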