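#' Fit a robust-design model by maximum likelihood
#'
#' Minimises [negLoglik()] with quasi-Newton optimisation (`nlminb`) from
#' `nStarts` dispersed initial coefficient vectors: one moment-style
#' heuristic start plus `nStarts - 1` random starts drawn logit-uniform on
#' (0.05, 0.95). Multiple starts guard against the multimodality that
#' Markovian-emigration likelihoods can show. The best optimum is kept; the
#' covariance matrix is the inverse of the numerically differentiated
#' observed information, and real-scale standard errors follow by the delta
#' method.
#'
#' AICc uses `-2 logLik + 2K + 2K(K+1)/(neff - K - 1)` with the effective
#' sample size `neff` summing, over individuals, the number of primaries
#' from first capture to the end of the study (`neffRule = "occasions"`);
#' `"individuals"` counts each individual once instead. Conventions for
#' conditional-likelihood sample size differ between implementations, so
#' both are available.
#'
#' Coefficients pushed to the logit boundary (|beta| > 10, e.g. under
#' perfect detection) are flagged in the convergence diagnostics and their
#' standard errors marked unreliable.
#'
#' @param structure a [ModelStructure-class].
#' @param ch a [CaptureHistory-class].
#' @param nStarts number of optimisation starts.
#' @param seed optional integer seed for the random starts.
#' @param neffRule `"occasions"` (default) or `"individuals"`.
#' @return a [RobustFit-class].
#' @export
fitModel <- function(structure, ch, nStarts = 10L, seed = NULL,
                     neffRule = c("occasions", "individuals")) {
  validObject(structure)
  validObject(ch)
  neffRule <- match.arg(neffRule)
  obj <- .negLoglikFactory(ch, structure)
  parmap <- attr(obj, "parmap")
  npar <- parmap$npar
  if (attr(obj, "nIndividuals") == 0L) stop("no individuals available for this structure")
  if (!is.null(seed)) set.seed(seed)

  smart <- numeric(npar)
  smart[grepl("^p", parmap$parNames)] <- qlogis(0.2)
  smart[grepl("^phi", parmap$parNames)] <- qlogis(0.8)
  smart[grepl("^gamma", parmap$parNames)] <- qlogis(0.2)
  starts <- c(
    list(smart),
    replicate(max(nStarts - 1L, 0L), qlogis(runif(npar, 0.05, 0.95)),
      simplify = FALSE
    )
  )

  runs <- lapply(starts, function(s) {
    tryCatch(
      nlminb(s, obj, control = list(
        eval.max = 5000L, iter.max = 1000L,
        rel.tol = 1e-10
      )),
      error = function(e) NULL
    )
  })
  ok <- !vapply(runs, is.null, logical(1))
  objectives <- vapply(runs, function(r) if (is.null(r)) Inf else r$objective, numeric(1))
  if (!any(is.finite(objectives) & objectives < 1e9)) {
    stop(
      "no optimisation start converged to a finite optimum; diagnostics: ",
      paste(round(objectives, 2), collapse = ", ")
    )
  }
  best <- runs[[which.min(objectives)]]
  beta <- best$par
  loglik <- -best$objective

  H <- tryCatch(optimHess(beta, obj), error = function(e) NULL)
  vc <- NULL
  if (!is.null(H)) {
    vc <- tryCatch(solve(H), error = function(e) NULL)
  }
  seUnreliable <- FALSE
  if (is.null(vc) || any(!is.finite(vc)) || any(diag(vc) < 0)) {
    vc <- matrix(NA_real_, npar, npar)
    seUnreliable <- TRUE
  }
  dimnames(vc) <- list(parmap$parNames, parmap$parNames)
  names(beta) <- parmap$parNames

  boundary <- abs(beta) > 10
  neff <- switch(neffRule,
    occasions = attr(obj, "neff"),
    individuals = attr(obj, "nIndividuals")
  )
  aiccVal <- -2 * loglik + 2 * npar + 2 * npar * (npar + 1) / (neff - npar - 1)

  real <- .realTable(beta, vc, parmap, ch@design)
  conv <- list(
    objectives = objectives, converged = ok,
    messages = vapply(runs, function(r) if (is.null(r)) "error" else r$message, character(1)),
    boundary = boundary, seUnreliable = seUnreliable || any(boundary)
  )
  if (any(boundary)) {
    warning(
      "estimate(s) at the logit boundary: ",
      paste(parmap$parNames[boundary], collapse = ", "),
      "; standard errors are unreliable"
    )
  }
  new("RobustFit",
    structure = structure, beta = beta, vcov = vc, loglik = loglik,
    npar = as.integer(npar), neff = neff, aicc = aiccVal, real = real,
    convergence = conv, data = ch, parmap = parmap
  )
}

# real-scale estimate table on the common (class, sex, year) grid
.realTable <- function(beta, vc, parmap, design) {
  years <- design@years
  T <- parmap$nPrimary
  nI <- parmap$nInterval
  rows <- list()
  cell <- function(class, sex, year, idx, fixVal = NA_real_) {
    if (is.na(idx)) {
      data.frame(
        class = class, sex = sex, year = year, estimate = fixVal,
        se = 0, fixed = TRUE, coef = NA_integer_, stringsAsFactors = FALSE
      )
    } else {
      est <- plogis(beta[idx])
      seB <- sqrt(vc[idx, idx])
      data.frame(
        class = class, sex = sex, year = year, estimate = est,
        se = est * (1 - est) * seB, fixed = FALSE, coef = idx,
        stringsAsFactors = FALSE
      )
    }
  }
  for (j in seq_len(nI)) {
    for (s in 1:2) {
      rows[[length(rows) + 1L]] <- cell(
        "phi", c("male", "female")[s], years[j],
        parmap$phiIdx[s, j]
      )
    }
    rows[[length(rows) + 1L]] <- cell(
      "gammaDP", "total", years[j], parmap$gdpIdx[j],
      parmap$gdpFix[j]
    )
    rows[[length(rows) + 1L]] <- cell(
      "gammaP", "total", years[j], parmap$gpIdx[j],
      parmap$gpFix[j]
    )
  }
  for (t in seq_len(T)) {
    for (s in 1:2) {
      rows[[length(rows) + 1L]] <- cell(
        "p", c("male", "female")[s], years[t],
        parmap$pIdx[s, t]
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @name RobustFit-accessors
#' @title Accessors for fitted robust-design models
#' @param x a [RobustFit-class] (or, for `modelLabel`, also a
#'   [ModelStructure-class]).
NULL

#' @rdname RobustFit-accessors
#' @export
setMethod("aicc", "RobustFit", function(x) x@aicc)

#' @rdname RobustFit-accessors
#' @export
setMethod("realEstimates", "RobustFit", function(x) x@real)

#' @rdname RobustFit-accessors
#' @export
setMethod("modelLabel", "RobustFit", function(x) modelLabel(x@structure))

setMethod("show", "RobustFit", function(object) {
  cat("RobustFit:", modelLabel(object), "\n")
  cat(sprintf(
    "  logLik %.3f on %d coefficients, AICc %.2f (neff %.0f)\n",
    object@loglik, object@npar, object@aicc, object@neff
  ))
  if (isTRUE(object@convergence$seUnreliable)) {
    cat("  note: standard errors flagged unreliable\n")
  }
  invisible(object)
})

.fingerprint <- function(ch) {
  paste(nrow(ch@sec), ncol(ch@sec), sum(ch@sec),
    paste(range(ch@design@years), collapse = "-"),
    sep = "/"
  )
}
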