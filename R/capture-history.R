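#' Assemble robust-design capture histories
#'
#' Cuts each primary occasion into its weekly secondary windows and records,
#' per individual and window, whether at least one independent event fell in
#' it (multiple events in the same window collapse to a single 1). Events
#' outside every primary (including pre-study events) are ignored but counted
#' in the build report. Cubs are excluded by default, since sex- and
#' survival-structured models concern the adult population; unknown-sex
#' individuals are retained unless `dropUnknownSex` and are excluded
#' automatically from sex-structured fits downstream.
#'
#' `events` is expected to be independence-filtered ([filterIndependent()])
#' first; binning is binary, so the histories themselves are insensitive to
#' that, but the companion [detectionSummary()] counts are not.
#'
#' @param events event data.frame.
#' @param design a [SurveyDesign-class].
#' @param adultsOnly drop `age_class == "cub"` events (default `TRUE`).
#' @param dropUnknownSex drop individuals of unknown sex entirely (default
#'   `FALSE`: they are kept, flagged, and skipped by sex-structured fits).
#' @return a [CaptureHistory-class].
#' @export
buildCaptureHistories <- function(events, design, adultsOnly = TRUE,
                                  dropUnknownSex = FALSE) {
  validObject(design)
  report <- list(nEvents = nrow(events), nCubs = 0L, nOutside = 0L, nUnknownSexDropped = 0L)
  if (adultsOnly && "age_class" %in% names(events)) {
    cub <- events$age_class == "cub"
    report$nCubs <- sum(cub)
    events <- events[!cub, , drop = FALSE]
  }
  if (dropUnknownSex) {
    unk <- events$sex == "unknown"
    report$nUnknownSexDropped <- length(unique(events$individual_id[unk]))
    events <- events[!unk, , drop = FALSE]
  }
  prim <- .primaryIndex(design, events$timestamp)
  report$nOutside <- sum(is.na(prim))
  if (report$nOutside > 0L) {
    warning(sprintf("%d event(s) fall outside all primary occasions", report$nOutside))
  }
  inw <- !is.na(prim)
  events <- events[inw, , drop = FALSE]
  prim <- prim[inw]
  K <- design@nSecondary
  offset <- c(0L, cumsum(K))[seq_along(K)]
  sec <- integer(0)
  ids <- unique(events$individual_id)
  mat <- matrix(0L,
    nrow = length(ids), ncol = sum(K),
    dimnames = list(ids, unlist(lapply(
      seq_along(K),
      function(i) sprintf("%d.%d", design@years[i], seq_len(K[i]))
    )))
  )
  if (nrow(events)) {
    week <- vapply(
      seq_len(nrow(events)),
      function(i) .secondaryIndex(design, prim[i], events$timestamp[i]),
      numeric(1)
    )
    col <- offset[prim] + week
    row <- match(events$individual_id, ids)
    mat[cbind(row, col)] <- 1L
  }
  sexTab <- tapply(events$sex, events$individual_id, function(s) {
    u <- unique(s)
    if (length(u) == 1L) u else setdiff(u, "unknown")[1]
  })
  indiv <- data.frame(
    id = ids,
    sex = as.character(sexTab[ids]),
    stringsAsFactors = FALSE
  )
  new("CaptureHistory",
    individuals = indiv, sec = mat, design = design,
    report = report
  )
}

#' @name CaptureHistory-accessors
#' @title Accessors for CaptureHistory objects
#' @param x a [CaptureHistory-class].
#' @return `individuals` returns the id/sex data.frame; `secondaryMatrix`
#'   the binary individuals x secondary-occasions matrix; `detectionCounts`
#'   the individuals x primaries matrix of per-primary detection counts
#'   (number of secondary occasions with a detection); `firstPrimary` the
#'   index of each individual's first primary with a detection;
#'   `buildReport` the ingestion counts recorded by
#'   [buildCaptureHistories()].
NULL

#' @rdname CaptureHistory-accessors
#' @export
setMethod("individuals", "CaptureHistory", function(x) x@individuals)

#' @rdname CaptureHistory-accessors
#' @export
setMethod("secondaryMatrix", "CaptureHistory", function(x) x@sec)

#' @rdname CaptureHistory-accessors
#' @export
setMethod("detectionCounts", "CaptureHistory", function(x) {
  K <- x@design@nSecondary
  grp <- rep(seq_along(K), K)
  out <- t(rowsum(t(x@sec), grp))
  colnames(out) <- x@design@years
  out
})

#' @rdname CaptureHistory-accessors
#' @export
setMethod("firstPrimary", "CaptureHistory", function(x) {
  counts <- detectionCounts(x)
  setNames(apply(counts > 0, 1L, which.max), x@individuals$id)
})

#' @rdname CaptureHistory-accessors
#' @export
setMethod("buildReport", "CaptureHistory", function(x) x@report)

setMethod("show", "CaptureHistory", function(object) {
  sx <- table(factor(object@individuals$sex, c("male", "female", "unknown")))
  cat(sprintf(
    "CaptureHistory: %d individuals (%d male, %d female, %d unknown), %d primaries\n",
    nrow(object@individuals), sx[["male"]], sx[["female"]], sx[["unknown"]],
    length(object@design@years)
  ))
  cat(sprintf(
    "  detections: %d occasion-level, %d secondary occasions total\n",
    sum(object@sec), ncol(object@sec)
  ))
  invisible(object)
})

#' Per-individual and per-survey detection summaries
#'
#' Computed on independence-filtered events. Returns per-individual,
#' per-primary counts of independent detections; per-survey totals of
#' individuals and detections by sex; and, when `nStations` is given, the
#' detections-per-location rate (independent detections divided by the number
#' of active stations) per individual and survey year, the quantity used to
#' compare residents with transients.
#'
#' @param events independence-filtered event data.frame.
#' @param design a [SurveyDesign-class].
#' @param nStations number of active camera stations per survey-year (single
#'   value or per-primary vector); `NULL` omits the rate.
#' @return list with data.frames `byIndividual` (`individual_id`, `sex`,
#'   `year`, `n`, and `ratePerLocation` when available) and `bySurvey`
#'   (`year`, `sex`, `nIndividuals`, `nDetections`).
#' @export
detectionSummary <- function(events, design, nStations = NULL) {
  prim <- .primaryIndex(design, events$timestamp)
  keep <- !is.na(prim)
  ev <- events[keep, , drop = FALSE]
  prim <- prim[keep]
  if (nrow(ev) == 0L) {
    return(list(
      byIndividual = data.frame(
        individual_id = character(), sex = character(),
        year = integer(), n = integer()
      ),
      bySurvey = data.frame(
        year = integer(), sex = character(),
        nIndividuals = integer(), nDetections = integer()
      )
    ))
  }
  ev$year <- design@years[prim]
  byInd <- aggregate(
    list(n = rep(1L, nrow(ev))),
    by = list(individual_id = ev$individual_id, sex = ev$sex, year = ev$year),
    FUN = sum
  )
  byInd <- byInd[order(byInd$individual_id, byInd$year), , drop = FALSE]
  rownames(byInd) <- NULL
  if (!is.null(nStations)) {
    ns <- rep_len(nStations, length(design@years))
    byInd$ratePerLocation <- byInd$n / ns[match(byInd$year, design@years)]
  }
  bySurvey <- aggregate(
    list(nDetections = byInd$n, nIndividuals = rep(1L, nrow(byInd))),
    by = list(year = byInd$year, sex = byInd$sex),
    FUN = sum
  )
  bySurvey <- bySurvey[order(bySurvey$year, bySurvey$sex), c("year", "sex", "nIndividuals", "nDetections")]
  rownames(bySurvey) <- NULL
  list(byIndividual = byInd, bySurvey = bySurvey)
}

#' Individual-by-year detection matrix
#'
#' Collapses a capture history to a binary individuals x surveyed-years
#' matrix, the input for residency classification and cohort decomposition.
#'
#' @param ch a [CaptureHistory-class].
#' @return binary matrix with individual ids as row names and surveyed years
#'   as column names.
#' @export
yearlyDetectionMatrix <- function(ch) {
  out <- (detectionCounts(ch) > 0) * 1L
  rownames(out) <- ch@individuals$id
  out
}
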