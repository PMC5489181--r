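#' AICc comparison table
#'
#' Ranks fitted models by AICc and attaches delta AICc, model likelihood
#' `exp(-delta / 2)` and Akaike weights
#' `exp(-delta_i / 2) / sum_j exp(-delta_j / 2)`. All fits must be of the
#' same capture-history data.
#'
#' @param fits list of [RobustFit-class] objects.
#' @return data.frame sorted by AICc: `model`, `npar`, `loglik`, `aicc`,
#'   `delta`, `modelLik`, `weight`.
#' @export
aiccWeights <- function(fits) {
  if (!length(fits)) stop("no fits supplied")
  fps <- vapply(fits, function(f) .fingerprint(f@data), character(1))
  if (length(unique(fps)) != 1L) {
    stop("fits were made on different data sets; AICc comparison is invalid")
  }
  a <- vapply(fits, aicc, numeric(1))
  tab <- data.frame(
    model = vapply(fits, modelLabel, character(1)),
    npar = vapply(fits, function(f) f@npar, integer(1)),
    loglik = vapply(fits, function(f) f@loglik, numeric(1)),
    aicc = a,
    stringsAsFactors = FALSE
  )
  tab <- cbind(tab, aiccWeightTable(a - min(a)))
  tab <- tab[order(tab$aicc), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Akaike weights from delta-AICc values
#'
#' The bare weight arithmetic, usable directly on published delta-AICc
#' columns: model likelihood `exp(-delta / 2)` and weights normalised over
#' the supplied candidate set. Weights are invariant to adding a constant
#' to every AICc value.
#'
#' @param delta numeric vector of AICc differences from the best model.
#' @return data.frame with columns `delta`, `modelLik`, `weight`.
#' @examples
#' aiccWeightTable(c(0, 2.08))$modelLik # 1.00, 0.35
#' @export
aiccWeightTable <- function(delta) {
  delta <- delta - min(delta)
  ml <- exp(-delta / 2)
  data.frame(delta = delta, modelLik = ml, weight = ml / sum(ml))
}

#' AICc model averaging with unconditional standard errors
#'
#' Averages real-scale parameters (and derived abundance) across fitted
#' models with Akaike weights: `theta_bar = sum w_i theta_i`, with the
#' Burnham-Anderson unconditional standard error
#' `sum w_i sqrt(var_i + (theta_i - theta_bar)^2)`. Averaging is done on the
#' real (probability) scale. With `top` set, only the `top` best-ranked
#' models enter and the weights are renormalised over them -- the study's
#' reporting convention averaged its top six models.
#'
#' @param fits list of [RobustFit-class] objects of the same data.
#' @param top optional number of top-ranked models to average over.
#' @return a [ModelAverage-class].
#' @export
modelAverage <- function(fits, top = NULL) {
  wtab <- aiccWeights(fits)
  ord <- order(vapply(fits, aicc, numeric(1)))
  fits <- fits[ord]
  if (!is.null(top)) {
    top <- min(top, length(fits))
    fits <- fits[seq_len(top)]
    wtab <- wtab[seq_len(top), , drop = FALSE]
    wtab$weight <- wtab$modelLik / sum(wtab$modelLik)
  }
  w <- wtab$weight

  grids <- lapply(fits, realEstimates)
  key <- function(g) paste(g$class, g$sex, g$year)
  k0 <- key(grids[[1]])
  for (g in grids[-1]) {
    if (!identical(key(g), k0)) stop("fits expose different real-parameter grids")
  }
  est <- sapply(grids, function(g) g$estimate)
  se <- sapply(grids, function(g) g$se)
  avg <- as.numeric(est %*% w)
  unc <- vapply(seq_len(nrow(est)), function(i) {
    sum(w * sqrt(se[i, ]^2 + (est[i, ] - avg[i])^2))
  }, numeric(1))
  estimates <- data.frame(
    class = grids[[1]]$class, sex = grids[[1]]$sex,
    year = grids[[1]]$year, estimate = avg, se = unc,
    stringsAsFactors = FALSE
  )

  abunds <- lapply(fits, derivedAbundance)
  Ns <- sapply(abunds, function(a) a$N)
  Nse <- sapply(abunds, function(a) a$se)
  ne <- abunds[[1]]$ne
  avgN <- as.numeric(Ns %*% w)
  uncN <- vapply(seq_len(nrow(Ns)), function(i) {
    sum(w * sqrt(Nse[i, ]^2 + (Ns[i, ] - avgN[i])^2))
  }, numeric(1))
  avgN[ne] <- NA_real_
  uncN[ne] <- NA_real_
  abundance <- data.frame(
    year = abunds[[1]]$year, sex = abunds[[1]]$sex,
    n = abunds[[1]]$n, N = avgN, se = uncN, ne = ne,
    stringsAsFactors = FALSE
  )
  new("ModelAverage", weights = wtab, estimates = estimates, abundance = abundance)
}

#' @rdname ModelAverage-class
#' @param x a [ModelAverage-class].
#' @export
setMethod("akaikeWeights", "ModelAverage", function(x) x@weights)

#' @rdname ModelAverage-class
#' @export
setMethod("averagedEstimates", "ModelAverage", function(x) x@estimates)

#' @rdname ModelAverage-class
#' @export
setMethod("abundanceTable", "ModelAverage", function(x) x@abundance)

setMethod("show", "ModelAverage", function(object) {
  cat(sprintf(
    "ModelAverage over %d models (top weight %.2f)\n",
    nrow(object@weights), max(object@weights$weight)
  ))
  print(object@weights[, c("model", "aicc", "delta", "weight")])
  invisible(object)
})
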