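# Independent oracles, deliberately implemented without reusing the package's
# likelihood machinery: explicit state-path enumeration, brute-force scans,
# exact small-sample null distributions by exhaustive enumeration.

# probability of a specific secondary history (given as per-primary detection
# counts) conditional on first detection at primary f, by summing over every
# alive/off/dead state path explicitly
statePathProb <- function(counts, K, phi, gdp, gp, p, dt = rep(1L, length(K) - 1L)) {
  T <- length(K)
  f <- which(counts > 0)[1]
  oneYear <- function(ph, gD, gP) {
    matrix(
      c(
        ph * (1 - gD), ph * gD, 1 - ph,
        ph * (1 - gP), ph * gP, 1 - ph,
        0, 0, 1
      ),
      3, 3,
      byrow = TRUE
    )
  }
  matPow <- function(M, k) {
    out <- diag(3)
    for (i in seq_len(k)) out <- out %*% M
    out
  }
  emit <- function(d, Kt, state, pt) {
    if (state == 1L) {
      return(pt^d * (1 - pt)^(Kt - d))
    }
    as.numeric(d == 0L)
  }
  pstar <- 1 - (1 - p[f])^K[f]
  first <- emit(counts[f], K[f], 1L, p[f]) / pstar
  if (f == T) {
    return(first)
  }
  later <- (f + 1):T
  nLater <- length(later)
  total <- 0
  paths <- expand.grid(rep(list(1:3), nLater))
  for (r in seq_len(nrow(paths))) {
    path <- as.integer(paths[r, ])
    pr <- 1
    prevState <- 1L
    for (k in seq_len(nLater)) {
      t <- later[k]
      M <- matPow(oneYear(phi[t - 1], gdp[t - 1], gp[t - 1]), dt[t - 1])
      pr <- pr * M[prevState, path[k]] * emit(counts[t], K[t], path[k], p[t])
      prevState <- path[k]
    }
    total <- total + pr
  }
  first * total
}

# sum of exp(historyLoglik) over every possible post-first-detection history,
# counting binomial multiplicity of each count pattern
enumHistorySum <- function(K, phi, gdp, gp, p, f, dt = rep(1L, length(K) - 1L)) {
  T <- length(K)
  ranges <- vector("list", T)
  for (t in seq_len(T)) {
    ranges[[t]] <- if (t < f) 0L else if (t == f) seq_len(K[t]) else 0:K[t]
  }
  grid <- expand.grid(ranges)
  total <- 0
  for (r in seq_len(nrow(grid))) {
    counts <- as.integer(grid[r, ])
    mult <- prod(choose(K, counts))
    total <- total + mult * exp(historyLoglik(counts, K, phi, gdp, gp, p, dt))
  }
  total
}

# quadratic-time independence filter: repeatedly take the earliest remaining
# event of each individual and delete everything less than the gap after it
bruteForceFilter <- function(events, gapHours = 24) {
  keepAll <- logical(nrow(events))
  for (id in unique(events$individual_id)) {
    idx <- which(events$individual_id == id)
    remaining <- idx[order(events$timestamp[idx])]
    while (length(remaining)) {
      first <- remaining[1]
      keepAll[first] <- TRUE
      gaps <- as.numeric(difftime(events$timestamp[remaining],
        events$timestamp[first],
        units = "hours"
      ))
      remaining <- remaining[gaps >= gapHours]
    }
  }
  out <- events[keepAll, , drop = FALSE]
  out <- out[order(out$individual_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# conditional CJS log-likelihood on presence/absence per primary with known
# per-primary detection probability pstar, by enumerating the death time
cjsLoglik <- function(presence, phi, pstar, dt = rep(1L, ncol(presence) - 1L)) {
  T <- ncol(presence)
  annSurv <- function(a, b) if (b < a) 1 else prod(phi[a:b]^dt[a:b])
  ll <- 0
  for (i in seq_len(nrow(presence))) {
    y <- presence[i, ]
    f <- which(y > 0)[1]
    if (f == T) next
    tot <- 0
    for (d in f:T) { # d = last primary the animal is alive for
      w <- annSurv(f, d - 1) * if (d == T) 1 else (1 - phi[d]^dt[d])
      obs <- 1
      if (d > f) {
        for (t in (f + 1):d) obs <- obs * ifelse(y[t] > 0, pstar[t], 1 - pstar[t])
      }
      if (d < T && any(y[(d + 1):T] > 0)) obs <- 0
      tot <- tot + w * obs
    }
    ll <- ll + log(tot)
  }
  ll
}

# grid-then-polish maximiser of the closed-population M0 conditional
# likelihood (single primary, K occasions, p = c)
m0OracleP <- function(counts, K) {
  nll <- function(p) {
    pstar <- 1 - (1 - p)^K
    -sum(counts * log(p) + (K - counts) * log(1 - p) - log(pstar))
  }
  grid <- seq(0.001, 0.999, by = 0.001)
  p0 <- grid[which.min(vapply(grid, nll, numeric(1)))]
  optimize(nll, c(max(p0 - 0.002, 1e-6), min(p0 + 0.002, 1 - 1e-6)), tol = 1e-10)$minimum
}

# exact two-sided signed-rank p-value by enumerating all sign assignments
signedRankExact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  vObs <- sum(r[d > 0])
  vAll <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m))[seq_len(n)]
    vAll[m + 1] <- sum(r[signs == 1L])
  }
  pLo <- mean(vAll <= vObs)
  pHi <- mean(vAll >= vObs)
  list(V = vObs, p = min(1, 2 * min(pLo, pHi)))
}

# exact two-sided rank-sum p-value by enumerating all group assignments;
# W is the Mann-Whitney U for the first sample, as stats::wilcox.test reports
rankSumExact <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  wObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- combn(length(pooled), nx)
  wAll <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  pLo <- mean(wAll <= wObs)
  pHi <- mean(wAll >= wObs)
  list(W = wObs, p = min(1, 2 * min(pLo, pHi)))
}

# longest run of detections over the supplied columns
runLengthOracle <- function(v) {
  best <- 0L
  run <- 0L
  for (z in v) {
    run <- if (z > 0) run + 1L else 0L
    best <- max(best, run)
  }
  best
}
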