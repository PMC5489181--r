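#' Derive abundance from a fitted model
#'
#' Abundance enters the conditional (Huggins-style) likelihood nowhere, so
#' it is derived per sex and primary occasion as `N = n / pstar`, where `n`
#' is the number of distinct individuals of that sex detected in the primary
#' and `pstar = 1 - (1 - p)^K` is the probability of at least one detection
#' over the primary's `K` secondary occasions at the fitted per-occasion
#' detection probability.
#'
#' The standard error combines the binomial sampling component
#' `n (1 - pstar) / pstar^2` with the detection-parameter uncertainty
#' propagated through the delta method. Sex-and-year cells with `n = 0` are
#' not estimable and flagged `ne`.
#'
#' @param fit a [RobustFit-class].
#' @return data.frame with one row per (year, sex): `n`, `p`, `pstar`, `N`,
#'   `se`, `ne`.
#' @examples
#' # n = 10 detected, p = 0.5 over K = 2 occasions: pstar = 0.75, N = 13.33
#' @export
derivedAbundance <- function(fit) {
  ch <- fit@data
  design <- ch@design
  D <- detectionCounts(ch)
  sex <- ch@individuals$sex
  K <- design@nSecondary
  parmap <- fit@parmap
  rows <- list()
  for (t in seq_along(design@years)) {
    for (s in 1:2) {
      sexName <- c("male", "female")[s]
      n <- sum(D[sex == sexName, t] > 0)
      idx <- parmap$pIdx[s, t]
      p <- plogis(fit@beta[idx])
      if (p <= 0) stop("fitted detection probability is zero; abundance undefined")
      pstar <- 1 - (1 - p)^K[t]
      if (n == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          year = design@years[t], sex = sexName, n = 0L, p = p,
          pstar = pstar, N = NA_real_, se = NA_real_, ne = TRUE,
          stringsAsFactors = FALSE
        )
        next
      }
      N <- n / pstar
      varEta <- fit@vcov[idx, idx]
      dpstar <- K[t] * (1 - p)^(K[t] - 1) * p * (1 - p) # d pstar / d eta
      varN <- n * (1 - pstar) / pstar^2 + (n / pstar^2 * dpstar)^2 * varEta
      rows[[length(rows) + 1L]] <- data.frame(
        year = design@years[t], sex = sexName, n = n, p = p,
        pstar = pstar, N = N, se = sqrt(varN), ne = FALSE,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
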