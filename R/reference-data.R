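#' Published model-averaged estimates from the jaguar monitoring program
#'
#' The model-averaged annual estimates reported for the 14-year jaguar
#' camera-trap monitoring program the package's presets are calibrated to:
#' per-year, per-sex apparent survival, per-occasion detection, derived
#' abundance (the 2002 female cell is not estimable -- no female was
#' detected that year) and the constant random temporary-emigration rate.
#' These printed values are the inputs for the derived-demography worked
#' example: feeding them through [demographyTable()] reproduces the
#' program's published annual rates of change and recruitment.
#'
#' @return list of data.frames: `abundance` (`year`, `sex`, `N`, `se`),
#'   `survival` (`year`, `sex`, `phi`, `se`), `detection` (`year`, `sex`,
#'   `p`, `se`), `gamma` (`year`, `gamma`, `se`).
#' @export
referenceEstimates <- function() {
  path <- system.file("extdata", "jaguar_model_averaged_estimates.csv",
    package = "camtrapRD", mustWork = TRUE
  )
  raw <- read.csv(path)
  long <- function(male, female, name) {
    out <- rbind(
      data.frame(year = raw$year, sex = "male", v = raw[[male[1]]], se = raw[[male[2]]]),
      data.frame(year = raw$year, sex = "female", v = raw[[female[1]]], se = raw[[female[2]]])
    )
    names(out)[3] <- name
    out[order(out$year, out$sex), , drop = FALSE]
  }
  list(
    abundance = long(c("N_male", "N_male_se"), c("N_female", "N_female_se"), "N"),
    survival = setNames(
      long(c("phi_male", "phi_male_se"), c("phi_female", "phi_female_se"), "phi"),
      c("year", "sex", "phi", "se")
    ),
    detection = long(c("p_male", "p_male_se"), c("p_female", "p_female_se"), "p"),
    gamma = data.frame(year = raw$year, gamma = raw$gamma, se = raw$gamma_se)
  )
}

#' Published model-selection table of the jaguar monitoring program
#'
#' The seven best-ranked robust-design structures reported for the 14-year
#' jaguar analysis with their AICc values, AICc differences, and the
#' reported Akaike weights and model likelihoods (for cross-checking the
#' package's [aiccWeightTable()] arithmetic).
#'
#' @return data.frame: `model`, `aicc`, `delta`, `weight_reported`,
#'   `modellik_reported`.
#' @export
referenceModelSelection <- function() {
  read.csv(
    system.file("extdata", "jaguar_model_selection.csv",
      package = "camtrapRD", mustWork = TRUE
    ),
    stringsAsFactors = FALSE
  )
}
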