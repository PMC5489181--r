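#' Configure the synthetic camera-trap population generator
#'
#' The generator emulates the statistical structure the robust-design
#' analysis assumes: an open population with constant annual apparent
#' survival, temporary emigration (random or Markovian), Poisson per-capita
#' recruitment, sex- and camera-era-specific per-occasion detection, a
#' resident/transient detection dichotomy, and event-level output (clustered
#' raw photographs at stations) that exercises the 24-hour independence
#' filter.
#'
#' Transients are modelled as a fraction of entrants with reduced
#' per-occasion detection (`transientDetMult`); by default they share the
#' same survival and emigration rates as residents -- their permanent
#' departures are part of apparent mortality, and the short observed tenure
#' of transients emerges from low detectability, movement and turnover.
#' Setting `transientLeaves = TRUE` instead makes them leave the population
#' permanently after a dwell of 1--2 years, which depresses realized
#' apparent survival below `phi`.
#'
#' @param design a [SurveyDesign-class].
#' @param nInitial named integer vector `c(male =, female =)`, initial
#'   on-grid cohort sizes.
#' @param recruitRate per-capita annual recruitment rate (Poisson).
#' @param phi annual apparent survival.
#' @param gammaMode `"random"` or `"markovian"`.
#' @param gammaDP probability an on-grid survivor is off-grid next year.
#' @param gammaP probability an off-grid survivor stays off-grid (ignored
#'   under `"random"`, where it equals `gammaDP`).
#' @param pFilm named per-occasion detection probabilities for film-era
#'   primaries, `c(male =, female =)`.
#' @param pDigital matrix of detection probabilities, rows `male`/`female`,
#'   one column per digital-era year (column names are years).
#' @param transientFraction fraction of entrants with the transient
#'   detection profile.
#' @param transientDetMult detection multiplier for transients.
#' @param transientLeaves transients leave permanently after 1--2 years.
#' @param nStations number of camera stations.
#' @param clusterRate each detection spawns `1 + Poisson(clusterRate)` raw
#'   events within a 6-hour window at one station.
#' @param seed default seed used when [simulatePopulation()] is called
#'   without one.
#' @return a validated configuration list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(design = jaguarSurveyDesign(),
                             nInitial = c(male = 18L, female = 18L),
                             recruitRate = 0.22,
                             phi = 0.78,
                             gammaMode = c("random", "markovian"),
                             gammaDP = 0.20,
                             gammaP = 0.20,
                             pFilm = c(male = 0.36, female = 0.07),
                             pDigital = NULL,
                             transientFraction = 0.3,
                             transientDetMult = 0.6,
                             transientLeaves = FALSE,
                             nStations = 19L,
                             clusterRate = 0.5,
                             seed = NULL) {
  gammaMode <- match.arg(gammaMode)
  validObject(design)
  digitalYears <- design@years[design@era == "digital"]
  if (is.null(pDigital)) {
    pDigital <- matrix(rep(pFilm, length(digitalYears)),
      nrow = 2L,
      dimnames = list(c("male", "female"), digitalYears)
    )
  }
  probs <- c(phi, gammaDP, gammaP, pFilm, pDigital, recruitRate * 0) # rate checked separately
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (recruitRate < 0) stop("recruitRate must be non-negative")
  if (nStations < 1L) stop("need at least one station")
  if (sum(nInitial) < 1L) stop("initial population must be non-empty")
  if (length(digitalYears) && !identical(
    sort(as.integer(colnames(pDigital))),
    sort(digitalYears)
  )) {
    stop("pDigital columns must cover the design's digital years")
  }
  structure(
    list(
      design = design, nInitial = nInitial, recruitRate = recruitRate,
      phi = phi, gammaMode = gammaMode, gammaDP = gammaDP,
      gammaP = if (gammaMode == "random") gammaDP else gammaP,
      pFilm = pFilm, pDigital = pDigital,
      transientFraction = transientFraction,
      transientDetMult = transientDetMult,
      transientLeaves = transientLeaves,
      nStations = as.integer(nStations), clusterRate = clusterRate,
      seed = seed
    ),
    class = "SimulationConfig"
  )
}

#' Preset configuration mirroring the 14-year jaguar study
#'
#' Default generator settings at the scale of the long-term jaguar
#' monitoring program: the 12-primary survey layout with the 2009--2010 gap
#' ([jaguarSurveyDesign()]), annual apparent survival 0.78, random temporary
#' emigration 0.20, film-era detection 0.36 (males) and 0.07 (females) per
#' weekly occasion with the study's year-specific digital-era values, a
#' balanced true sex ratio (the strongly male-biased *detected* sex ratio
#' emerges from detectability alone), 19 stations, and a transient fraction
#' of 0.3 with detection multiplier 0.6 (the observed transient/resident
#' ratio of detections per location).
#'
#' @return a `"SimulationConfig"`.
#' @export
jaguarPreset <- function() {
  simulationConfig(
    design = jaguarSurveyDesign(),
    pDigital = matrix(
      c(
        0.47, 0.27, 0.40, 0.33, 0.37,
        0.05, 0.06, 0.12, 0.16, 0.16
      ),
      nrow = 2L, byrow = TRUE,
      dimnames = list(c("male", "female"), 2011:2015)
    ),
    seed = 20020215L
  )
}

#' Simulate a camera-trap study with a truth ledger
#'
#' Runs the generative model of [simulationConfig()]: the initial cohort
#' starts on-grid; each subsequent calendar year (including unsurveyed gap
#' years) individuals survive with probability `phi`, survivors move
#' between on- and off-grid states per the emigration mode, and new
#' recruits enter on-grid at the per-capita Poisson rate. In each surveyed
#' primary, every on-grid individual is detected on each weekly secondary
#' occasion with its sex/era/profile-specific probability; each detection
#' spawns `1 + Poisson(clusterRate)` raw events within a 6-hour window at a
#' uniformly chosen station. Event times sit away from the weekly window
#' edges by more than the independence gap, so 24-hour filtering collapses
#' each cluster to one event without ever erasing a detected occasion --
#' the truth ledger is exactly recoverable from the emitted events.
#'
#' @param config a `"SimulationConfig"`.
#' @param seed integer seed; falls back to `config$seed`; one of the two is
#'   required.
#' @return list with `events` (data.frame as from [parseEvents()]) and
#'   `ledger`, a list of `states` (individual x calendar-year matrix over
#'   `"U"` not-yet-recruited, `"A"` on-grid, `"O"` off-grid, `"D"` dead),
#'   `individuals` (id, sex, transient profile, entry year), `detections`
#'   (true per-occasion detection indicators), `summary` (per surveyed
#'   year: alive, on-grid, detected) and `config`.
#' @export
simulatePopulation <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (is.null(seed)) stop("a seed is required for reproducibility")
  set.seed(seed)
  design <- config$design
  calYears <- seq(min(design@years), max(design@years))
  nY <- length(calYears)

  id <- character(0)
  sexV <- character(0)
  trans <- logical(0)
  dwell <- integer(0)
  entry <- integer(0)
  counter <- c(male = 0L, female = 0L)
  newIndiv <- function(sex, n, year) {
    if (n == 0L) {
      return(invisible(NULL))
    }
    pre <- if (sex == "male") "M" else "F"
    ids <- sprintf("%s%04d", pre, counter[[sex]] + seq_len(n))
    counter[[sex]] <<- counter[[sex]] + n
    id <<- c(id, ids)
    sexV <<- c(sexV, rep(sex, n))
    trans <<- c(trans, runif(n) < config$transientFraction)
    dwell <<- c(dwell, sample(1:2, n, replace = TRUE))
    entry <<- c(entry, rep(year, n))
    ids
  }
  for (s in c("male", "female")) newIndiv(s, config$nInitial[[s]], calYears[1])
  states <- matrix("U", length(id), nY, dimnames = list(id, calYears))
  states[, 1] <- "A"

  for (yi in 2:nY) {
    prev <- states[, yi - 1]
    alive <- prev %in% c("A", "O")
    nxt <- rep("D", length(prev))
    nxt[prev == "U"] <- "U"
    for (i in which(alive)) {
      if (config$transientLeaves && trans[i] &&
        (calYears[yi] - entry[i]) >= dwell[i]) {
        nxt[i] <- "D" # permanent departure; apparent death
        next
      }
      if (runif(1) > config$phi) {
        nxt[i] <- "D"
        next
      }
      gOff <- if (config$gammaMode == "random") {
        config$gammaDP
      } else if (prev[i] == "A") config$gammaDP else config$gammaP
      nxt[i] <- if (runif(1) < gOff) "O" else "A"
    }
    aliveBySex <- c(
      male = sum(alive & sexV[seq_along(alive)] == "male"),
      female = sum(alive & sexV[seq_along(alive)] == "female")
    )
    newRows <- list()
    for (s in c("male", "female")) {
      nNew <- rpois(1L, config$recruitRate * aliveBySex[[s]])
      if (nNew > 0L) {
        ids <- newIndiv(s, nNew, calYears[yi])
        block <- matrix("U", nNew, nY, dimnames = list(ids, calYears))
        block[, yi] <- "A"
        newRows[[length(newRows) + 1L]] <- block
      }
    }
    states[, yi] <- nxt[seq_len(nrow(states))]
    if (length(newRows)) states <- rbind(states, do.call(rbind, newRows))
  }

  # detection within surveyed primaries
  detRows <- list()
  evRows <- list()
  for (t in seq_along(design@years)) {
    year <- design@years[t]
    yi <- match(year, calYears)
    K <- design@nSecondary[t]
    onGrid <- which(states[, yi] == "A")
    for (i in onGrid) {
      pBase <- if (design@era[t] == "film") {
        config$pFilm[[sexV[i]]]
      } else {
        config$pDigital[sexV[i], as.character(year)]
      }
      pEff <- pBase * if (trans[i]) config$transientDetMult else 1
      hits <- which(runif(K) < pEff)
      if (!length(hits)) next
      detRows[[length(detRows) + 1L]] <- data.frame(
        id = id[i], year = year, week = hits, stringsAsFactors = FALSE
      )
      for (wk in hits) {
        baseOff <- (wk - 1) * 7 + runif(1, 1.25, 5.5) # days; >= 24 h + cluster from edges
        nExtra <- rpois(1L, config$clusterRate)
        offs <- baseOff + c(0, sort(runif(nExtra, 0, 0.25)))
        station <- sprintf("S%02d", sample.int(config$nStations, 1L))
        evRows[[length(evRows) + 1L]] <- data.frame(
          individual_id = id[i], sex = sexV[i], age_class = "adult",
          station_id = station,
          timestamp = as.POSIXct(design@start[t], tz = "UTC") + offs * 86400,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  detections <- if (length(detRows)) do.call(rbind, detRows) else {
    data.frame(id = character(), year = integer(), week = integer())
  }
  events <- if (length(evRows)) do.call(rbind, evRows) else {
    data.frame(
      individual_id = character(), sex = character(),
      age_class = character(), station_id = character(),
      timestamp = as.POSIXct(character(), tz = "UTC")
    )
  }
  events <- events[order(events$individual_id, events$timestamp), , drop = FALSE]
  rownames(events) <- NULL

  surveyedIdx <- match(design@years, calYears)
  surv <- states[, surveyedIdx, drop = FALSE]
  summary <- data.frame(
    year = design@years,
    alive = colSums(surv == "A" | surv == "O"),
    onGrid = colSums(surv == "A"),
    detected = vapply(
      design@years,
      function(y) length(unique(detections$id[detections$year == y])), integer(1)
    )
  )
  list(
    events = events,
    ledger = list(
      states = states,
      individuals = data.frame(
        id = id, sex = sexV, transient = trans,
        entry = entry, stringsAsFactors = FALSE
      ),
      detections = detections,
      summary = summary,
      config = config
    )
  )
}
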