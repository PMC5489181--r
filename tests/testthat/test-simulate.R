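test_that("deterministic edge cases: immortality, zero detection, empty start", {
  cfg <- smallSimConfig(phi = 1, gammaDP = 0, recruitRate = 0)
  sim <- simulatePopulation(cfg, seed = 1)
  st <- sim$ledger$states
  expect_true(all(st == "A")) # everyone on-grid every year
  expect_equal(nrow(st), sum(cfg$nInitial))

  cfg0 <- smallSimConfig(pFilm = c(male = 0, female = 0))
  sim0 <- simulatePopulation(cfg0, seed = 2)
  expect_equal(nrow(sim0$events), 0L)
  expect_equal(nrow(sim0$ledger$detections), 0L)

  expect_error(
    simulationConfig(nInitial = c(male = 0L, female = 0L)),
    "non-empty"
  )
  expect_error(simulatePopulation(smallSimConfig()), "seed")
})

test_that("simulation is seed-reproducible", {
  a <- simulatePopulation(smallSimConfig(), seed = 77)
  b <- simulatePopulation(smallSimConfig(), seed = 77)
  expect_identical(a$events, b$events)
  expect_identical(a$ledger$states, b$ledger$states)
  c <- simulatePopulation(smallSimConfig(), seed = 78)
  expect_false(identical(a$events, c$events))
})

test_that("ledger marginals match the emitted events", {
  sim <- simulatePopulation(smallSimConfig(), seed = 13)
  led <- sim$ledger
  expect_setequal(unique(sim$events$individual_id), unique(led$detections$id))
  # detections occur only for on-grid individual-years
  for (r in seq_len(nrow(led$detections))) {
    expect_equal(led$states[led$detections$id[r], as.character(led$detections$year[r])], "A")
  }
  # dead is absorbing
  for (i in seq_len(nrow(led$states))) {
    s <- led$states[i, ]
    dead <- which(s == "D")
    if (length(dead)) expect_true(all(s[min(dead):length(s)] == "D"))
  }
  # independence-filtered events reproduce the per-occasion truth 1:1
  ch <- buildCaptureHistories(filterIndependent(sim$events), smallSimConfig()$design)
  expect_equal(sum(secondaryMatrix(ch)), nrow(led$detections))
})

test_that("markovian mode with gamma' = gamma'' reproduces the random-mode process", {
  cfgR <- smallSimConfig(gammaMode = "random", gammaDP = 0.25)
  cfgM <- smallSimConfig(gammaMode = "markovian", gammaDP = 0.25, gammaP = 0.25)
  a <- simulatePopulation(cfgR, seed = 5)
  b <- simulatePopulation(cfgM, seed = 5)
  expect_identical(a$ledger$states, b$ledger$states)
  expect_identical(a$events, b$events)
})

test_that("realized rates agree with the configured survival and emigration", {
  cfg <- smallSimConfig(
    years = 2002:2011, nInitial = c(male = 40L, female = 40L),
    recruitRate = 0.2, phi = 0.78, gammaDP = 0.2
  )
  surv <- c(0, 0)
  offF <- alive <- 0
  for (s in 1:12) {
    out <- simulatePopulation(cfg, seed = 600 + s)
    led <- out$ledger$states
    entry <- setNames(out$ledger$individuals$entry, out$ledger$individuals$id)
    yrs <- as.integer(colnames(led))
    for (y in seq_len(ncol(led) - 1)) {
      al <- led[, y] %in% c("A", "O")
      surv <- surv + c(sum(led[al, y + 1] != "D"), sum(al))
    }
    # emigration state is stationary only after the (forced on-grid) entry year
    post <- led[, -1, drop = FALSE]
    postEntry <- outer(entry[rownames(led)], yrs[-1], FUN = "<")
    offF <- offF + sum(post == "O" & postEntry)
    alive <- alive + sum((post == "O" | post == "A") & postEntry)
  }
  pSurv <- surv[1] / surv[2]
  mcse <- sqrt(0.78 * 0.22 / surv[2])
  expect_lt(abs(pSurv - 0.78), 4 * mcse)
  # random emigration: off-grid fraction among established alive animals
  expect_lt(abs(offF / alive - 0.2), 4 * sqrt(0.2 * 0.8 / alive) + 0.01)
})

test_that("the study-scale preset has the published layout and a male-biased detected ratio", {
  cfg <- jaguarPreset()
  d <- cfg$design
  expect_equal(length(designYears(d)), 12L)
  expect_equal(designYears(d), c(2002:2008, 2011:2015))
  expect_equal(unname(intervalYears(d)[as.character(2008)]), 3L)
  expect_equal(unname(cameraEra(d)[as.character(2002:2008)]), rep("film", 7))
  expect_equal(unname(cameraEra(d)[as.character(2011:2015)]), rep("digital", 5))

  # detected-per-survey sex ratio is male-biased in film years despite the
  # balanced true sex ratio: a pure detectability artifact
  ratios <- numeric(0)
  for (s in 1:5) {
    sim <- simulatePopulation(cfg, seed = 300 + s)
    det <- sim$ledger$detections
    det$sex <- sim$ledger$individuals$sex[match(det$id, sim$ledger$individuals$id)]
    for (y in 2002:2008) {
      ind <- unique(det[det$year == y, c("id", "sex")])
      if (sum(ind$sex == "female") > 0) {
        ratios <- c(ratios, sum(ind$sex == "male") / sum(ind$sex == "female"))
      }
    }
  }
  expect_gt(mean(ratios), 1.5)
})
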