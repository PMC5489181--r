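#' Annual state-transition matrix of the open robust design
#'
#' Between primary occasions an animal moves among three states: on-grid
#' (available for detection), off-grid (alive but temporarily outside the
#' sampled area) and dead (absorbing; apparent death, i.e. death or
#' permanent emigration). With annual apparent survival `phi`, probability
#' `gammaDP` (gamma'') that an on-grid survivor is off-grid next year, and
#' probability `gammaP` (gamma') that an off-grid survivor stays off-grid,
#' the one-year matrix has rows
#' `A: (phi (1-gammaDP), phi gammaDP, 1-phi)`,
#' `O: (phi (1-gammaP), phi gammaP, 1-phi)`,
#' `D: (0, 0, 1)`. For an interval of `dt` years (a survey gap) the
#' one-year matrix is raised to the `dt`-th power, applying the annual rates
#' each unobserved year.
#'
#' @param phi,gammaDP,gammaP probabilities in `[0, 1]`.
#' @param dt positive integer interval length in years.
#' @return 3x3 row-stochastic matrix with dimnames `A`, `O`, `D`.
#' @examples
#' transitionMatrix(0.78, 0.2, 0.2)
#' @export
transitionMatrix <- function(phi, gammaDP, gammaP, dt = 1L) {
  if (dt < 1L) stop("dt must be a positive whole number of years")
  stopifnot(phi >= 0, phi <= 1, gammaDP >= 0, gammaDP <= 1, gammaP >= 0, gammaP <= 1)
  M <- matrix(
    c(
      phi * (1 - gammaDP), phi * gammaDP, 1 - phi,
      phi * (1 - gammaP), phi * gammaP, 1 - phi,
      0, 0, 1
    ),
    nrow = 3L, byrow = TRUE,
    dimnames = list(c("A", "O", "D"), c("A", "O", "D"))
  )
  out <- M
  for (i in seq_len(dt - 1L)) out <- out %*% M
  out
}

#' Within-primary emission probability of a secondary history
#'
#' Under the closed-population part of the robust design, an on-grid animal
#' is detected independently on each secondary occasion with probability `p`
#' (capture and recapture equal), so a binary history `y` has probability
#' `prod(p^y (1-p)^(1-y))`. Off-grid and dead animals cannot be detected:
#' their emission probability is 1 for the all-zero history and 0 otherwise.
#'
#' @param y binary vector over the primary's secondary occasions.
#' @param state `"A"`, `"O"` or `"D"`.
#' @param p per-occasion detection probability.
#' @return a probability.
#' @export
emissionProb <- function(y, state, p) {
  stopifnot(p >= 0, p <= 1, all(y %in% c(0, 1)))
  if (state == "A") {
    return(prod(p^y * (1 - p)^(1 - y)))
  }
  as.numeric(all(y == 0))
}

#' Log-likelihood contribution of one capture history
#'
#' Huggins-style conditional likelihood of one individual's robust-design
#' history, conditioned on the animal being on-grid and detected at least
#' once in its first detected primary `f`: the first-primary term is the
#' closed emission probability divided by `pstar_f = 1 - (1 - p_f)^K_f`, and
#' later primaries are handled by a forward pass over the three states using
#' [transitionMatrix()] (with the design's whole-year intervals) and
#' [emissionProb()]. Abundance stays out of the likelihood and is derived
#' afterwards.
#'
#' This scalar implementation is the package's reference form of the
#' likelihood; [fitModel()] uses an algebraically identical vectorised
#' engine.
#'
#' @param counts integer vector of per-primary detection counts (detected
#'   secondary occasions) for the individual.
#' @param K integer vector of secondary-occasion counts per primary.
#' @param phi numeric vector of per-interval apparent survival.
#' @param gammaDP,gammaP numeric vectors of per-interval emigration
#'   probabilities.
#' @param p numeric vector of per-primary detection probability for this
#'   individual's group.
#' @param dt integer vector of interval lengths in years (default all 1).
#' @return the log-probability of the history given first detection at `f`.
#' @export
historyLoglik <- function(counts, K, phi, gammaDP, gammaP, p,
                          dt = rep(1L, length(K) - 1L)) {
  T <- length(K)
  f <- which(counts > 0)[1]
  if (is.na(f)) stop("history has no detection; the likelihood conditions on first capture")
  pstar <- 1 - (1 - p[f])^K[f]
  if (pstar <= 0) stop("pstar is zero at the first detection; detection parameters degenerate")
  ll <- counts[f] * log(p[f]) + (K[f] - counts[f]) * log(1 - p[f]) - log(pstar)
  if (f < T) {
    alpha <- c(1, 0, 0)
    for (t in (f + 1):T) {
      M <- transitionMatrix(phi[t - 1], gammaDP[t - 1], gammaP[t - 1], dt[t - 1])
      alpha <- as.numeric(alpha %*% M)
      eA <- p[t]^counts[t] * (1 - p[t])^(K[t] - counts[t])
      zero <- as.numeric(counts[t] == 0)
      alpha <- alpha * c(eA, zero, zero)
    }
    ll <- ll + log(sum(alpha))
  }
  ll
}

# Vectorised negative log-likelihood over all individuals, with identical
# histories (same sex group, first primary and count pattern) collapsed to
# weighted unique patterns. Returns a function of beta plus the prepared
# data as attributes.
.negLoglikFactory <- function(ch, structure, design = ch@design) {
  parmap <- .buildParMap(structure, design)
  D <- detectionCounts(ch)
  sex <- ch@individuals$sex
  if (parmap$usesSex) {
    keep <- sex != "unknown"
    D <- D[keep, , drop = FALSE]
    sex <- sex[keep]
  }
  if (nrow(D) == 0L) {
    obj <- function(beta) 0
    attr(obj, "parmap") <- parmap
    attr(obj, "neff") <- 0
    attr(obj, "nIndividuals") <- 0L
    return(obj)
  }
  sexIdx <- ifelse(sex == "female", 2L, 1L)
  T <- ncol(D)
  K <- design@nSecondary
  f <- apply(D > 0, 1L, which.max)

  key <- paste(sexIdx, f, apply(D, 1L, paste, collapse = ","))
  uk <- !duplicated(key)
  w <- as.numeric(table(key)[key[uk]])
  D <- D[uk, , drop = FALSE]
  sexIdx <- sexIdx[uk]
  f <- f[uk]
  N <- nrow(D)
  Kmat <- matrix(K, N, T, byrow = TRUE)
  neff <- sum(w * (T - f + 1))

  obj <- function(beta) {
    if (any(!is.finite(beta))) {
      return(1e10)
    }
    rp <- .realParams(beta, parmap)
    pN <- rp$p[cbind(
      rep(sexIdx, T),
      rep(seq_len(T), each = N)
    )]
    dim(pN) <- c(N, T)
    logEA <- D * log(pN) + (Kmat - D) * log1p(-pN)
    pstarN <- 1 - (1 - pN)^Kmat
    ll <- logEA[cbind(seq_len(N), f)] - log(pstarN[cbind(seq_len(N), f)])
    if (T > 1L) {
      M <- vector("list", 2L)
      for (s in 1:2) {
        M[[s]] <- lapply(seq_len(T - 1L), function(j) {
          transitionMatrix(rp$phi[s, j], rp$gdp[j], rp$gp[j], parmap$dt[j])
        })
      }
      alpha <- matrix(0, N, 3L)
      alpha[f == 1L, 1L] <- 1
      EA <- exp(logEA)
      for (t in 2:T) {
        act <- f < t
        for (s in 1:2) {
          r <- act & sexIdx == s
          if (any(r)) alpha[r, ] <- alpha[r, , drop = FALSE] %*% M[[s]][[t - 1L]]
        }
        zero <- D[, t] == 0
        alpha[act, 1L] <- alpha[act, 1L] * EA[act, t]
        alpha[act, 2L] <- alpha[act, 2L] * zero[act]
        alpha[act, 3L] <- alpha[act, 3L] * zero[act]
        init <- f == t
        if (any(init)) {
          alpha[init, 1L] <- 1
          alpha[init, 2L] <- 0
          alpha[init, 3L] <- 0
        }
      }
      ll <- ll + log(rowSums(alpha))
    }
    val <- -sum(w * ll)
    if (!is.finite(val)) {
      return(1e10)
    }
    val
  }
  attr(obj, "parmap") <- parmap
  attr(obj, "neff") <- neff
  attr(obj, "nIndividuals") <- sum(w)
  obj
}

#' Negative log-likelihood of a robust-design model
#'
#' The objective minimised by [fitModel()]: minus the sum over individuals
#' of [historyLoglik()], with real parameters obtained from the logit-scale
#' coefficient vector through the structure's parameter map (fixed
#' parameters, e.g. the no-emigration gammas, bypass the link). Individuals
#' of unknown sex are excluded whenever the structure involves sex.
#'
#' @param beta logit-scale coefficient vector, ordered as in
#'   `parameterNames(structure, design)`.
#' @param structure a [ModelStructure-class].
#' @param ch a [CaptureHistory-class].
#' @param design the survey design; defaults to the history's.
#' @return the negative log-likelihood (a large finite penalty when the
#'   objective degenerates numerically).
#' @export
negLoglik <- function(beta, structure, ch, design = ch@design) {
  obj <- .negLoglikFactory(ch, structure, design)
  if (length(beta) != attr(obj, "parmap")$npar) {
    stop(sprintf(
      "beta has length %d but the structure has %d coefficients",
      length(beta), attr(obj, "parmap")$npar
    ))
  }
  obj(beta)
}

#' Coefficient names of a model structure on a design
#'
#' @param structure a [ModelStructure-class].
#' @param design a [SurveyDesign-class].
#' @return character vector naming the logit-scale coefficients, in the
#'   order expected by [negLoglik()] and reported by [fitModel()].
#' @export
parameterNames <- function(structure, design) {
  .buildParMap(structure, design)$parNames
}
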