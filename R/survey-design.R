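#' Construct a survey design
#'
#' @param years integer vector of surveyed calendar years (strictly
#'   increasing). Unsurveyed years are simply absent; the model bridges them
#'   with multi-year transitions.
#' @param start survey start date per primary; either `Date` or
#'   `"YYYY-MM-DD"` strings. Defaults to 15 February of each year, a typical
#'   dry-season start.
#' @param days integer survey duration per primary, in days.
#' @param nSecondary number of weekly secondary occasions per primary.
#'   Defaults to `floor(days / 7)`: secondary windows are consecutive 7-day
#'   blocks from the start date, and a final remainder shorter than a week is
#'   merged into the last full week.
#' @param era camera technology per primary, `"film"` or `"digital"`; a
#'   single value is recycled.
#' @return a [SurveyDesign-class].
#' @examples
#' d <- surveyDesign(2002:2004, days = c(70, 84, 84), era = "film")
#' secondaryCounts(d)
#' @export
surveyDesign <- function(years, start = NULL, days = 70L, nSecondary = NULL,
                         era = "film") {
  years <- as.integer(years)
  n <- length(years)
  if (is.null(start)) start <- as.Date(sprintf("%d-02-15", years))
  start <- as.Date(start)
  days <- as.integer(rep_len(days, n))
  if (is.null(nSecondary)) nSecondary <- pmax(2L, days %/% 7L)
  nSecondary <- as.integer(rep_len(nSecondary, n))
  era <- rep_len(era, n)
  new("SurveyDesign",
    years = years, start = start, days = days,
    nSecondary = nSecondary, era = era
  )
}

#' The 14-year jaguar monitoring survey layout
#'
#' Survey design of the long-term jaguar camera-trap monitoring program the
#' package's presets are calibrated to: twelve annual dry-season primary
#' occasions, 2002--2008 and 2011--2015 (no surveys in 2009--2010), weekly
#' secondary occasions, film cameras through 2008 and digital cameras from
#' 2011. Survey durations ranged from 59 to 98 days; the year-long 2013
#' survey enters through its 100-day dry-season subsample (14 weekly
#' occasions, with the 2-day remainder merged into the final week).
#'
#' @return a [SurveyDesign-class] with 12 primaries.
#' @export
jaguarSurveyDesign <- function() {
  years <- c(2002:2008, 2011:2015)
  weeks <- c(10L, 12L, 12L, 13L, 14L, 12L, 9L, 11L, 12L, 14L, 12L, 13L)
  days <- weeks * 7L
  days[years == 2013] <- 100L # 14 weeks + 2-day remainder merged
  surveyDesign(years,
    days = days, nSecondary = weeks,
    era = ifelse(years <= 2008, "film", "digital")
  )
}

#' @name SurveyDesign-accessors
#' @title Accessors for SurveyDesign objects
#' @param x a [SurveyDesign-class].
#' @return `designYears`, `secondaryCounts`, `cameraEra`, `primaryStarts`
#'   return per-primary vectors; `intervalYears` returns the whole-year
#'   interval between consecutive primaries (length one less than the number
#'   of primaries).
NULL

#' @rdname SurveyDesign-accessors
#' @export
setMethod("designYears", "SurveyDesign", function(x) x@years)

#' @rdname SurveyDesign-accessors
#' @export
setMethod("secondaryCounts", "SurveyDesign", function(x) {
  setNames(x@nSecondary, x@years)
})

#' @rdname SurveyDesign-accessors
#' @export
setMethod("cameraEra", "SurveyDesign", function(x) setNames(x@era, x@years))

#' @rdname SurveyDesign-accessors
#' @export
setMethod("primaryStarts", "SurveyDesign", function(x) setNames(x@start, x@years))

#' @rdname SurveyDesign-accessors
#' @export
setMethod("intervalYears", "SurveyDesign", function(x) {
  if (length(x@years) < 2L) {
    return(integer(0))
  }
  setNames(diff(x@years), head(x@years, -1L))
})

setMethod("show", "SurveyDesign", function(object) {
  cat(sprintf(
    "SurveyDesign: %d primaries, %d--%d\n",
    length(object@years), min(object@years), max(object@years)
  ))
  gaps <- which(diff(object@years) > 1L)
  if (length(gaps)) {
    cat(sprintf(
      "  gaps: %s\n",
      paste(sprintf(
        "%d->%d", object@years[gaps],
        object@years[gaps + 1L]
      ), collapse = ", ")
    ))
  }
  cat(sprintf(
    "  secondary occasions: %s\n",
    paste(object@nSecondary, collapse = " ")
  ))
  cat(sprintf("  era: %s\n", paste(substr(object@era, 1, 1), collapse = " ")))
  invisible(object)
})

# secondary window index of an event time within primary i, or NA if outside
.secondaryIndex <- function(design, primary, when) {
  off <- as.numeric(difftime(when, design@start[primary], units = "days"))
  idx <- floor(off / 7) + 1
  idx[off < 0 | off >= design@days[primary]] <- NA_integer_
  pmin(idx, design@nSecondary[primary])
}

# primary occasion containing each event time (NA when outside all primaries)
.primaryIndex <- function(design, when) {
  out <- rep(NA_integer_, length(when))
  for (i in seq_along(design@years)) {
    off <- as.numeric(difftime(when, design@start[i], units = "days"))
    out[off >= 0 & off < design@days[i]] <- i
  }
  out
}
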