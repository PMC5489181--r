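# Shared fixtures: tiny designs, hand-built capture histories, and a small,
# fast simulation configuration used where the full study-scale preset would
# be wasteful.

tinyDesign <- function(years = 2002:2004, K = 2L, era = "film") {
  surveyDesign(years, days = 7L * rep_len(K, length(years)), nSecondary = K, era = era)
}

chFromSec <- function(sec, sexes, design, ids = NULL) {
  sec <- as.matrix(sec)
  storage.mode(sec) <- "integer"
  if (is.null(ids)) ids <- sprintf("i%03d", seq_len(nrow(sec)))
  K <- secondaryCounts(design)
  colnames(sec) <- unlist(lapply(
    seq_along(K),
    function(j) sprintf("%d.%d", designYears(design)[j], seq_len(K[[j]]))
  ))
  rownames(sec) <- ids
  new("CaptureHistory",
    individuals = data.frame(id = ids, sex = sexes, stringsAsFactors = FALSE),
    sec = sec, design = design, report = list()
  )
}

smallSimConfig <- function(years = 2002:2007, K = 6L, nInitial = c(male = 15L, female = 15L),
                           phi = 0.8, gammaDP = 0.15, recruitRate = 0.2,
                           pFilm = c(male = 0.35, female = 0.15), ...) {
  simulationConfig(
    design = tinyDesign(years, K),
    nInitial = nInitial, phi = phi, gammaDP = gammaDP,
    recruitRate = recruitRate, pFilm = pFilm, ...
  )
}

eventsDF <- function(id, sex, station, hours, origin = "2002-03-01 00:00:00") {
  n <- length(hours)
  data.frame(
    individual_id = rep_len(id, n), sex = rep_len(sex, n),
    age_class = rep_len("adult", n), station_id = rep_len(station, n),
    timestamp = as.POSIXct(origin, tz = "UTC") + hours * 3600,
    stringsAsFactors = FALSE
  )
}
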