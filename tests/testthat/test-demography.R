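# The published model-averaged abundance and survival estimates of the
# 14-year jaguar program serve as fixed inputs; the demography pipeline must
# reproduce the program's published annual rates, recruitment and summaries.

refLambda <- function() {
  ref <- referenceEstimates()
  lambdaSeries(ref$abundance)
}

test_that("annual rates of change reproduce the published series", {
  lam <- refLambda()
  get <- function(g, y) lam$lambda[lam$group == g & lam$year == y]
  expect_equal(round(get("male", 2003), 2), 1.55) # 14.16 / 9.16
  expect_equal(round(get("male", 2002), 2), 0.81)
  expect_equal(round(get("female", 2006), 2), 5.57)
  # the 2002 total treats the inestimable female cell as zero, flagged
  expect_equal(round(get("total", 2002), 2), 1.19)
  expect_match(lam$note[lam$group == "total" & lam$year == 2002], "inestimable")
  # female 2002 rate is undefined (no abundance estimate)
  expect_true(is.na(get("female", 2002)))
  # no rate spans the unsurveyed gap: 2008 and 2011 pair with nothing
  expect_false(any(lam$year %in% c(2008, 2009, 2010)))
})

test_that("lambda is scale-free and undefined at zero abundance", {
  ref <- referenceEstimates()
  doubled <- ref$abundance
  doubled$N <- doubled$N * 2
  expect_equal(lambdaSeries(doubled)$lambda, refLambda()$lambda)

  zero <- data.frame(year = c(2002, 2003), sex = "male", N = c(0, 5))
  expect_true(is.na(lambdaSeries(zero)$lambda[1]))
})

test_that("geometric mean rates match the published summaries and AM-GM holds", {
  lam <- refLambda()
  gm <- function(g) geometricMeanLambda(lam$lambda[lam$group == g])
  expect_equal(round(gm("male")$gmean, 2), 0.98)
  expect_equal(round(gm("female")$gmean, 2), 1.06)
  expect_equal(round(gm("total")$gmean, 2), 1.04)
  expect_equal(round(gm("male")$varN, 2), 0.07)
  expect_equal(gm("male")$n, 10L)

  flat <- geometricMeanLambda(rep(1, 6))
  expect_equal(flat$gmean, 1)
  expect_equal(flat$varN1, 0)
  expect_error(geometricMeanLambda(c(1.2, 0)), "non-positive")

  set.seed(4)
  for (i in 1:10) {
    x <- runif(8, 0.2, 3)
    expect_lte(geometricMeanLambda(x)$gmean, mean(x))
  }
  expect_equal(geometricMeanLambda(rep(1.3, 5))$gmean, 1.3)
})

test_that("recruitment reproduces the published values, flooring and conventions", {
  ref <- referenceEstimates()
  B <- recruits(ref$abundance, ref$survival)
  get <- function(g, y) B$recruits[B$group == g & B$year == y]
  expect_equal(round(get("male", 2003), 1), 6.9) # 14.16 - 9.16 * 0.79
  expect_equal(get("male", 2007), 0) # negative difference floored
  expect_match(B$note[B$group == "male" & B$year == 2007], "floored")
  expect_lt(B$unfloored[B$group == "male" & B$year == 2007], 0)
  expect_equal(round(get("female", 2003), 1), 8.7)
  # inestimable 2002 female abundance enters the published table as zero
  expect_equal(get("female", 2002), 0)
  expect_equal(round(get("total", 2002), 1), 0.2)
  # totals are sums of per-sex floored values
  expect_equal(round(get("total", 2004), 1), 4.1)

  # without the floor, the algebraic identity holds exactly
  Bu <- recruits(ref$abundance, ref$survival, floor = FALSE)
  male <- Bu[Bu$group == "male" & !is.na(Bu$recruits), ]
  for (r in seq_len(nrow(male))) {
    y <- male$year[r]
    Nt <- ref$abundance$N[ref$abundance$sex == "male" & ref$abundance$year == y]
    Nn <- ref$abundance$N[ref$abundance$sex == "male" & ref$abundance$year == y + 1]
    ph <- ref$survival$phi[ref$survival$sex == "male" & ref$survival$year == y]
    expect_equal(male$recruits[r], Nn - Nt * ph, tolerance = 1e-12)
  }
})

test_that("recruitment summaries match the published means and variances", {
  ref <- referenceEstimates()
  B <- recruits(ref$abundance, ref$survival)
  s <- recruitSummary(B)
  expect_equal(round(s$mean[s$group == "male"], 1), 3.3)
  expect_equal(round(s$mean[s$group == "female"], 1), 2.8)
  expect_equal(round(s$mean[s$group == "total"], 1), 6.1)
  expect_equal(s$var[s$group == "total"], 36.0, tolerance = 0.5)
  expect_equal(s$n, rep(10L, 3))

  allZero <- data.frame(year = 2002:2005, group = "male", recruits = 0)
  z <- recruitSummary(allZero)
  expect_equal(z$mean, 0)
  expect_equal(z$var, 0)
})

test_that("minimum ages and survivorship follow the two-year adult assumption", {
  expect_equal(minimumAge(2002, 2014), 14L)
  expect_equal(minimumAge(2005, 2005), 2L)
  expect_error(minimumAge(2005, 2004), "precedes")
  expect_equal(round(survivorship(0.78, 11), 2), 0.07)
})

test_that("cohort decomposition conserves counts and labels the gap cohort", {
  years <- c(2002:2008, 2011:2015)
  m <- matrix(0L, 2, length(years), dimnames = list(c("a", "b"), years))
  m["a", as.character(2002:2005)] <- 1L
  m["b", as.character(c(2011, 2013))] <- 1L
  ct <- cohortTable(m)
  expect_equal(sum(ct$counts$count[ct$counts$cohort == "2002"]), 4L)
  expect_equal(ct$individuals$cohort[ct$individuals$id == "b"], "2009/2011")
  expect_equal(ct$individuals$minAge[ct$individuals$id == "a"], 5L)

  set.seed(12)
  big <- matrix(rbinom(50 * 12, 1, 0.3), 50, dimnames = list(sprintf("j%02d", 1:50), years))
  big[rowSums(big) == 0, 1] <- 1L
  ctBig <- cohortTable(big)
  perYear <- tapply(ctBig$counts$count, ctBig$counts$year, sum)
  expect_equal(as.integer(perYear[as.character(years)]), unname(colSums(big)))
  # brute-force recount of one cohort-year cell
  firstYear <- years[apply(big > 0, 1, which.max)]
  want <- sum(big[, "2006"] > 0 & firstYear == 2004)
  got <- ctBig$counts$count[ctBig$counts$year == 2006 & ctBig$counts$cohort == "2004"]
  expect_equal(if (length(got)) got else 0L, want)
})

test_that("the combined demography table carries the published summary block", {
  ref <- referenceEstimates()
  tab <- demographyTable(ref$abundance, ref$survival)
  expect_equal(round(tab$lambda.male[tab$year == 2003], 2), 1.55)
  expect_equal(round(tab$recruits.total[tab$year == 2003], 1), 15.6)
  s <- attr(tab, "summary")
  expect_equal(round(s$gmeanLambda[s$group == "total"], 2), 1.04)
  expect_equal(round(s$mean[s$group == "male"], 1), 3.3)
})
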