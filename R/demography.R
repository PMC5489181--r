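#' Annual finite rate of population change
#'
#' `lambda_t = N_{t+1} / N_t` from an abundance series, computed only across
#' consecutive calendar years that were both surveyed and estimable; survey
#' gaps and inestimable entries yield `NA` (a dash in reports), never an
#' extrapolated multi-year rate. `lambda` is scale-free: multiplying every
#' abundance by a constant leaves it unchanged.
#'
#' The `total` group sums the per-sex abundances; when a sex is inestimable
#' in a year (typically because no individual of that sex was detected) it
#' contributes 0 to that year's total, and the affected entry is annotated
#' -- the convention used in the study's summary table.
#'
#' @param abundance data.frame with columns `year`, `sex`, `N` (`NA` for
#'   inestimable), e.g. from [abundanceTable()] or [derivedAbundance()].
#' @return data.frame: `year`, `group` (`male`/`female`/`total`), `lambda`,
#'   `note`.
#' @export
lambdaSeries <- function(abundance) {
  series <- .groupSeries(abundance)
  out <- list()
  for (g in names(series)) {
    s <- series[[g]]
    yrs <- s$year
    for (i in seq_along(yrs)) {
      if (!((yrs[i] + 1L) %in% yrs)) next
      j <- which(yrs == yrs[i] + 1L)
      lam <- if (is.na(s$N[i]) || is.na(s$N[j]) || s$N[i] == 0) NA_real_ else s$N[j] / s$N[i]
      note <- ""
      if (is.na(lam)) {
        note <- "inestimable abundance"
      } else if (s$partial[i] || s$partial[j]) note <- "total treats inestimable sex as 0"
      out[[length(out) + 1L]] <- data.frame(
        year = yrs[i], group = g, lambda = lam, note = note,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, out)
  out[order(out$group, out$year), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

# split an abundance table into per-sex series plus a summed total series
.groupSeries <- function(abundance) {
  stopifnot(all(c("year", "sex", "N") %in% names(abundance)))
  sexes <- intersect(c("male", "female"), unique(abundance$sex))
  series <- list()
  for (s in sexes) {
    a <- abundance[abundance$sex == s, , drop = FALSE]
    a <- a[order(a$year), , drop = FALSE]
    series[[s]] <- data.frame(year = a$year, N = a$N, partial = FALSE)
  }
  if (length(sexes) > 1L) {
    yrs <- sort(unique(abundance$year))
    tot <- vapply(yrs, function(y) {
      sum(abundance$N[abundance$year == y], na.rm = TRUE)
    }, numeric(1))
    partial <- vapply(yrs, function(y) {
      any(is.na(abundance$N[abundance$year == y]))
    }, logical(1))
    series$total <- data.frame(year = yrs, N = tot, partial = partial)
  }
  series
}

#' Geometric mean rate of change and its variance
#'
#' `exp(mean(log(lambda)))` over the defined (non-`NA`) annual rates. The
#' dispersion is reported as the plain variance of the `lambda` values in
#' both conventions -- population (`varN`, divisor `n`) and sample
#' (`varN1`, divisor `n - 1`) -- since reasonable summaries of a short
#' demographic series use either.
#'
#' @param lambda numeric vector of annual rates (`NA`s dropped); optionally
#'   named by year for error reporting.
#' @return list with `gmean`, `varN`, `varN1`, `n`.
#' @export
geometricMeanLambda <- function(lambda) {
  lam <- lambda[!is.na(lambda)]
  if (any(lam <= 0)) {
    bad <- names(lam)[lam <= 0]
    stop(
      "non-positive lambda",
      if (length(bad) && nzchar(bad[1])) paste0(" at ", paste(bad, collapse = ", ")) else ""
    )
  }
  n <- length(lam)
  m <- mean(lam)
  list(
    gmean = exp(mean(log(lam))),
    varN = sum((lam - m)^2) / n,
    varN1 = if (n > 1L) sum((lam - m)^2) / (n - 1L) else NA_real_,
    n = n
  )
}

#' Annual recruitment from abundance and survival
#'
#' New entries to the sampled population between consecutive surveyed years:
#' `B_t = N_{t+1} - N_t * phi_t`, floored at zero (sampling noise can push
#' the difference negative; the unfloored value is retained in `unfloored`
#' for diagnostics). Years whose `N_t` is inestimable get `B_t = 0` with an
#' annotation, and the `total` group is the sum of the per-sex floored
#' values -- both conventions matching the study's published recruitment
#' table.
#'
#' @param abundance data.frame `year`, `sex`, `N`.
#' @param survival data.frame `year`, `sex`, `phi`: apparent survival from
#'   `year` to `year + 1` (typically model-averaged estimates).
#' @param floor truncate negative recruitment at zero (default `TRUE`).
#' @return data.frame: `year`, `group`, `recruits`, `unfloored`, `note`.
#' @export
recruits <- function(abundance, survival, floor = TRUE) {
  stopifnot(all(c("year", "sex", "phi") %in% names(survival)))
  sexes <- intersect(c("male", "female"), unique(abundance$sex))
  out <- list()
  for (s in sexes) {
    a <- abundance[abundance$sex == s, , drop = FALSE]
    a <- a[order(a$year), , drop = FALSE]
    for (i in seq_len(nrow(a))) {
      y <- a$year[i]
      j <- which(a$year == y + 1L)
      if (!length(j)) next
      phi <- survival$phi[survival$sex == s & survival$year == y]
      if (!length(phi) || is.na(phi)) {
        out[[length(out) + 1L]] <- data.frame(
          year = y, group = s, recruits = NA_real_, unfloored = NA_real_,
          note = "no survival estimate", stringsAsFactors = FALSE
        )
        next
      }
      if (is.na(a$N[i])) {
        out[[length(out) + 1L]] <- data.frame(
          year = y, group = s, recruits = 0, unfloored = NA_real_,
          note = "inestimable abundance treated as 0", stringsAsFactors = FALSE
        )
        next
      }
      b <- a$N[j] - a$N[i] * phi
      out[[length(out) + 1L]] <- data.frame(
        year = y, group = s,
        recruits = if (floor) max(0, b) else b, unfloored = b,
        note = if (floor && b < 0) "floored at 0" else "", stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, out)
  if (length(sexes) > 1L && !is.null(out)) {
    yrs <- sort(unique(out$year))
    tot <- lapply(yrs, function(y) {
      rows <- out[out$year == y, , drop = FALSE]
      if (any(is.na(rows$recruits))) {
        return(NULL)
      }
      data.frame(
        year = y, group = "total", recruits = sum(rows$recruits),
        unfloored = sum(rows$unfloored, na.rm = TRUE),
        note = "", stringsAsFactors = FALSE
      )
    })
    out <- rbind(out, do.call(rbind, tot))
  }
  out <- out[order(out$group, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summaries of annual recruitment
#'
#' Arithmetic mean, sample variance (divisor `n - 1`), range and count of
#' the defined annual recruitment values, per group.
#'
#' @param recruitTable output of [recruits()].
#' @return data.frame: `group`, `mean`, `var`, `min`, `max`, `n`.
#' @export
recruitSummary <- function(recruitTable) {
  out <- lapply(split(recruitTable, recruitTable$group), function(d) {
    b <- d$recruits[!is.na(d$recruits)]
    if (length(b) < 2L) stop("need at least 2 defined years per group")
    data.frame(
      group = d$group[1], mean = mean(b), var = var(b),
      min = min(b), max = max(b), n = length(b), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Minimum age from first and last detection years
#'
#' Adults are assumed to be at least 2 years old at first solo detection
#' (young stay with their mother for about their first 24 months), so an
#' individual first seen in year `first` and last seen in year `last` was at
#' least `(last - first) + 2` years old at last detection.
#'
#' @param first,last integer detection years, `last >= first`; vectorised.
#' @return integer minimum ages.
#' @examples
#' minimumAge(2002, 2014) # 14
#' @export
minimumAge <- function(first, last) {
  if (any(last < first)) stop("last detection year precedes first")
  (last - first) + 2L
}

#' Fraction surviving a span of years at constant annual survival
#'
#' @param phi annual apparent survival.
#' @param nYears span in years.
#' @return `phi ^ nYears`.
#' @examples
#' survivorship(0.78, 11) # about 0.07: few 2-year-olds reach age 13
#' @export
survivorship <- function(phi, nYears) phi^nYears

#' First-detection cohort decomposition
#'
#' Assigns each individual to the cohort of its first detection year and
#' counts, for every surveyed year, the individuals detected that year by
#' cohort. A cohort first seen in the first surveyed year after a gap is
#' ambiguous -- the animal may have arrived during the unsurveyed years --
#' so its label spans the gap (e.g. `"2009/2011"` for a 2011 first
#' detection after a 2009--2010 gap).
#'
#' @param yearMat binary individuals x surveyed-years matrix with year
#'   column names ([yearlyDetectionMatrix()]).
#' @return list with `individuals` (`id`, `first`, `last`, `minAge`,
#'   `cohort`) and `counts` (`year`, `cohort`, `count`); per-year count sums
#'   equal the column sums of `yearMat`.
#' @export
cohortTable <- function(yearMat) {
  years <- as.integer(colnames(yearMat))
  stopifnot(!anyNA(years))
  lab <- as.character(years)
  if (length(years) > 1L) {
    gap <- c(FALSE, diff(years) > 1L)
    lab[gap] <- sprintf("%d/%d", years[which(gap) - 1L] + 1L, years[gap])
  }
  firstIdx <- apply(yearMat > 0, 1L, which.max)
  lastIdx <- ncol(yearMat) + 1L - apply(yearMat[, rev(seq_along(years)), drop = FALSE] > 0, 1L, which.max)
  indiv <- data.frame(
    id = rownames(yearMat),
    first = years[firstIdx], last = years[lastIdx],
    minAge = minimumAge(years[firstIdx], years[lastIdx]),
    cohort = lab[firstIdx], stringsAsFactors = FALSE
  )
  counts <- list()
  for (t in seq_along(years)) {
    det <- yearMat[, t] > 0
    if (!any(det)) next
    tab <- table(lab[firstIdx[det]])
    counts[[length(counts) + 1L]] <- data.frame(
      year = years[t], cohort = names(tab), count = as.integer(tab),
      stringsAsFactors = FALSE
    )
  }
  counts <- do.call(rbind, counts)
  rownames(counts) <- NULL
  list(individuals = indiv, counts = counts)
}

#' Annual change and recruitment in one table
#'
#' Convenience wrapper combining [lambdaSeries()] and [recruits()] into a
#' wide per-year table, with per-group summaries ([geometricMeanLambda()],
#' [recruitSummary()]) attached as the `"summary"` attribute.
#'
#' @inheritParams recruits
#' @return wide data.frame (`year`, `lambda.*`, `recruits.*`) with a
#'   `summary` attribute.
#' @export
demographyTable <- function(abundance, survival, floor = TRUE) {
  lam <- lambdaSeries(abundance)
  rec <- recruits(abundance, survival, floor = floor)
  yrs <- sort(unique(c(lam$year, rec$year)))
  wide <- data.frame(year = yrs)
  for (g in c("male", "female", "total")) {
    wide[[paste0("lambda.", g)]] <- lam$lambda[match(
      paste(yrs, g),
      paste(lam$year, lam$group)
    )]
    wide[[paste0("recruits.", g)]] <- rec$recruits[match(
      paste(yrs, g),
      paste(rec$year, rec$group)
    )]
  }
  summ <- lapply(c("male", "female", "total"), function(g) {
    gm <- geometricMeanLambda(lam$lambda[lam$group == g])
    data.frame(
      group = g, gmeanLambda = gm$gmean, lambdaVarN = gm$varN,
      lambdaVarN1 = gm$varN1, nLambda = gm$n, stringsAsFactors = FALSE
    )
  })
  summ <- do.call(rbind, summ)
  summ <- merge(summ, recruitSummary(rec), by = "group", sort = FALSE)
  attr(wide, "summary") <- summ
  wide
}
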