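#' @import methods
#' @importFrom stats plogis qlogis nlminb optim optimHess rbinom rpois runif
#'   setNames aggregate lm pf anova var sd median wilcox.test complete.cases
#' @importFrom utils read.csv write.csv head
NULL

#' Survey design: primary occasions, secondary occasions, camera eras
#'
#' A `SurveyDesign` describes the temporal layout of a multi-year
#' capture-recapture study: one primary occasion (survey season) per surveyed
#' year, each divided into consecutive week-long secondary occasions, with the
#' camera technology (film or digital) recorded per primary. Unsurveyed years
#' appear only implicitly, as intervals of more than one year between
#' consecutive primaries; the model applies per-year survival and movement
#' transitions across such gaps.
#'
#' @slot years integer vector of surveyed calendar years, strictly increasing.
#' @slot start `Date` vector, start date of each primary.
#' @slot days integer vector, survey duration of each primary in days.
#' @slot nSecondary integer vector, number of secondary (weekly) occasions
#'   per primary; a final remainder shorter than a week is merged into the
#'   last full week, so `nSecondary` is `floor(days / 7)`.
#' @slot era character vector, `"film"` or `"digital"` per primary.
#' @export
setClass("SurveyDesign",
  representation(
    years = "integer",
    start = "Date",
    days = "integer",
    nSecondary = "integer",
    era = "character"
  )
)

setValidity("SurveyDesign", function(object) {
  msg <- character()
  n <- length(object@years)
  if (n < 1L) msg <- c(msg, "at least one primary occasion is required")
  if (any(diff(object@years) < 1L)) {
    msg <- c(msg, "years must be strictly increasing")
  }
  if (length(object@start) != n || length(object@days) != n ||
    length(object@nSecondary) != n || length(object@era) != n) {
    msg <- c(msg, "all slots must have one entry per primary")
  }
  if (any(object@nSecondary < 2L)) {
    msg <- c(msg, "each primary needs >= 2 secondary occasions (closed estimation needs recaptures)")
  }
  if (!all(object@era %in% c("film", "digital"))) {
    msg <- c(msg, "era must be 'film' or 'digital'")
  }
  if (any(object@days < 7L * object@nSecondary)) {
    msg <- c(msg, "survey duration shorter than its secondary occasions")
  }
  if (n > 1L) {
    ends <- object@start + object@days
    if (any(object@start[-1L] < ends[-n])) {
      msg <- c(msg, "primary occasions overlap")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Robust-design capture histories
#'
#' Binary individual-by-occasion detection records, organised as one row per
#' individual and one column per secondary occasion (grouped by primary), with
#' per-individual sex labels. Built from independence-filtered detection
#' events by [buildCaptureHistories()].
#'
#' @slot individuals data.frame with columns `id` and `sex`
#'   (`male`/`female`/`unknown`), one row per detected individual.
#' @slot sec integer 0/1 matrix, individuals x total secondary occasions, with
#'   column names `"<year>.<week>"`.
#' @slot design the [SurveyDesign-class] the columns refer to.
#' @slot report list of ingestion counts (events outside all primaries,
#'   excluded cubs, etc.).
#' @export
setClass("CaptureHistory",
  representation(
    individuals = "data.frame",
    sec = "matrix",
    design = "SurveyDesign",
    report = "list"
  )
)

setValidity("CaptureHistory", function(object) {
  msg <- character()
  if (!all(c("id", "sex") %in% names(object@individuals))) {
    msg <- c(msg, "individuals needs 'id' and 'sex' columns")
  }
  if (nrow(object@individuals) != nrow(object@sec)) {
    msg <- c(msg, "one matrix row per individual required")
  }
  if (ncol(object@sec) != sum(object@design@nSecondary)) {
    msg <- c(msg, "matrix columns must match the design's secondary occasions")
  }
  if (length(object@sec) && !all(object@sec %in% c(0L, 1L))) {
    msg <- c(msg, "detection entries must be 0/1")
  }
  if (nrow(object@sec) && any(rowSums(object@sec) < 1L)) {
    msg <- c(msg, "every individual must have at least one detection")
  }
  if (!all(object@individuals$sex %in% c("male", "female", "unknown"))) {
    msg <- c(msg, "sex must be male/female/unknown")
  }
  if (length(msg)) msg else TRUE
})

#' Robust-design model structure
#'
#' Specifies which factors drive each parameter class of the open robust
#' design: apparent survival `phi`, temporary emigration (`gamma''` =
#' probability an on-grid animal is off-grid next primary, `gamma'` =
#' probability an off-grid animal stays off), and per-occasion detection `p`
#' (capture and recapture constrained equal, `p = c`).
#'
#' Supported factor specifications:
#' \describe{
#'   \item{`phi`}{`"."`, `"sex"`, `"time"`, `"sex*time"`, `"sex(time/.)"`
#'     (time-varying for males, constant for females), `"sex(./time)"` (the
#'     reverse).}
#'   \item{`gammaMode`}{`"random"` (`gamma' = gamma''`), `"markovian"`
#'     (both free), `"none"` (fixed `gamma'' = 0`, `gamma' = 1`).}
#'   \item{`gammaTime`}{`"."` or `"time"`.}
#'   \item{`p`}{`"."`, `"sex"`, `"time"`, `"era"`, `"sex*era"`,
#'     `"sex*time"`, `"era(./time)"`, `"sex*era(./time)"` -- the
#'     `era(./time)` forms keep detection constant across film-era primaries
#'     and year-specific across digital-era primaries.}
#' }
#' @export
setClass("ModelStructure",
  representation(
    phi = "character",
    gammaMode = "character",
    gammaTime = "character",
    p = "character"
  )
)

setValidity("ModelStructure", function(object) {
  msg <- character()
  if (!object@phi %in% c(".", "sex", "time", "sex*time", "sex(time/.)", "sex(./time)")) {
    msg <- c(msg, sprintf("unsupported phi structure '%s'", object@phi))
  }
  if (!object@gammaMode %in% c("random", "markovian", "none")) {
    msg <- c(msg, sprintf("unsupported gamma mode '%s'", object@gammaMode))
  }
  if (!object@gammaTime %in% c(".", "time")) {
    msg <- c(msg, sprintf("unsupported gamma time structure '%s'", object@gammaTime))
  }
  if (!object@p %in% c(
    ".", "sex", "time", "era", "sex*era", "sex*time",
    "era(./time)", "sex*era(./time)"
  )) {
    msg <- c(msg, sprintf("unsupported p structure '%s'", object@p))
  }
  if (length(msg)) msg else TRUE
})

#' Fitted robust-design model
#'
#' Maximum-likelihood fit of a [ModelStructure-class] to a
#' [CaptureHistory-class], on the logit scale, with the variance-covariance
#' matrix taken as the inverse of the numerically differentiated observed
#' information. Real-scale estimates (with delta-method standard errors) are
#' tabulated in `real`; derived abundance is obtained separately with
#' [derivedAbundance()].
#'
#' @slot structure the fitted [ModelStructure-class].
#' @slot beta numeric, estimated logit-scale coefficients.
#' @slot vcov matrix, covariance of `beta`.
#' @slot loglik numeric, maximised log-likelihood.
#' @slot npar integer, number of estimated coefficients.
#' @slot neff numeric, effective sample size used for AICc.
#' @slot aicc numeric.
#' @slot real data.frame of real-scale estimates: `class`
#'   (`phi`/`gammaDP`/`gammaP`/`p`), `sex`, `year`, `estimate`, `se`, `fixed`.
#' @slot convergence list of optimizer diagnostics (per-start objective
#'   values, convergence codes, boundary flags).
#' @slot data the [CaptureHistory-class] used (kept for derived abundance).
#' @slot parmap internal coefficient index map.
#' @export
setClass("RobustFit",
  representation(
    structure = "ModelStructure",
    beta = "numeric",
    vcov = "matrix",
    loglik = "numeric",
    npar = "integer",
    neff = "numeric",
    aicc = "numeric",
    real = "data.frame",
    convergence = "list",
    data = "CaptureHistory",
    parmap = "list"
  )
)

#' AICc-weighted model average
#'
#' Model-averaged real-scale parameters with unconditional standard errors in
#' the Burnham-Anderson form, plus the AICc comparison table the weights came
#' from.
#'
#' @slot weights data.frame: model label, AICc, delta AICc, Akaike weight,
#'   model likelihood.
#' @slot estimates data.frame of averaged real parameters (`class`, `sex`,
#'   `year`, `estimate`, `se`).
#' @slot abundance data.frame of averaged derived abundance per sex and year.
#' @export
setClass("ModelAverage",
  representation(
    weights = "data.frame",
    estimates = "data.frame",
    abundance = "data.frame"
  )
)
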