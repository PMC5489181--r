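#' Classify residents and transients from yearly detections
#'
#' A local resident is an individual detected in the survey area for at
#' least `minRun` (default 3) consecutive surveyed years; everyone else is a
#' transient of the study area (possibly a resident beyond its boundary).
#' Runs are computed over surveyed years only: unsurveyed years are skipped,
#' not counted as absences, so detections either side of a survey gap count
#' as consecutive -- absence of data is not absence of the animal.
#'
#' Classification is restricted to individuals detected within `window`
#' (the study used 2003--2007, its longest uninterrupted run of surveys),
#' but runs may extend through `buffer` surveyed years either side of the
#' window, so that detections just outside the window secure residency
#' status within it.
#'
#' @param yearMat binary individuals x surveyed-years matrix
#'   ([yearlyDetectionMatrix()]).
#' @param window integer years defining the evaluation window; must be
#'   covered by the matrix.
#' @param minRun consecutive-year threshold for residency.
#' @param buffer surveyed years either side of the window whose detections
#'   may extend a run.
#' @param sex optional named vector (by individual id) joined into the
#'   output.
#' @return data.frame: `id`, `sex` (if given), `yearsDetected`, `first`,
#'   `last`, `span`, `longestRun`, `status`.
#' @export
classifyResidency <- function(yearMat, window = 2003:2007, minRun = 3L,
                              buffer = 1L, sex = NULL) {
  years <- as.integer(colnames(yearMat))
  if (min(window) < min(years) || max(window) > max(years)) {
    stop("window years not all covered by the detection matrix")
  }
  window <- intersect(window, years) # unsurveyed years inside the window are skipped
  below <- rev(years[years < min(window)])
  above <- years[years > max(window)]
  extYears <- sort(c(
    window,
    head(below, buffer),
    head(above, buffer)
  ))
  ext <- yearMat[, as.character(extYears), drop = FALSE]
  inWindow <- yearMat[, as.character(window), drop = FALSE]
  keep <- rowSums(inWindow) > 0
  ext <- ext[keep, , drop = FALSE]
  out <- data.frame(id = rownames(ext), stringsAsFactors = FALSE)
  if (!is.null(sex)) out$sex <- unname(sex[out$id])
  det <- ext > 0
  out$yearsDetected <- rowSums(det)
  firstIdx <- apply(det, 1L, which.max)
  lastIdx <- ncol(det) + 1L - apply(det[, rev(seq_len(ncol(det))), drop = FALSE], 1L, which.max)
  out$first <- extYears[firstIdx]
  out$last <- extYears[lastIdx]
  out$span <- out$last - out$first
  out$longestRun <- apply(det, 1L, .longestRun)
  out$status <- ifelse(out$longestRun >= minRun, "resident", "transient")
  rownames(out) <- NULL
  out
}

# longest run of TRUEs over consecutive (surveyed) positions
.longestRun <- function(x) {
  best <- run <- 0L
  for (v in x) {
    run <- if (v) run + 1L else 0L
    best <- max(best, run)
  }
  best
}

#' Two-group Monte-Carlo permutation test
#'
#' Two-sided permutation test of a group-difference statistic (difference of
#' means by default): group labels are reshuffled `nPerm` times and the
#' Monte-Carlo p-value is `(1 + #{|T*| >= |T|}) / (nPerm + 1)`. The p-value
#' is invariant to relabelling the groups and to affine transformation of
#' the data; constant pooled data give p = 1.
#'
#' @param a,b numeric vectors, both non-empty.
#' @param statistic function of two vectors; default difference of means.
#' @param nPerm number of permutations, at least 999.
#' @param seed optional integer seed for reproducibility.
#' @return list: `statistic` (observed), `p`, `nPerm`.
#' @export
permutationTest <- function(a, b, statistic = function(x, y) mean(x) - mean(y),
                            nPerm = 9999L, seed = NULL) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (nPerm < 999L) stop("use at least 999 permutations")
  if (!is.null(seed)) set.seed(seed)
  pooled <- c(a, b)
  na <- length(a)
  obs <- statistic(a, b)
  if (all(pooled == pooled[1])) {
    return(list(statistic = obs, p = 1, nPerm = nPerm))
  }
  eps <- 1e-12 * max(1, abs(obs))
  hits <- 0L
  for (i in seq_len(nPerm)) {
    idx <- sample.int(length(pooled), na)
    st <- statistic(pooled[idx], pooled[-idx])
    if (abs(st) >= abs(obs) - eps) hits <- hits + 1L
  }
  list(statistic = obs, p = (1 + hits) / (nPerm + 1), nPerm = nPerm)
}

#' Paired Wilcoxon signed-rank test
#'
#' Wrapper over [stats::wilcox.test()] with the standard zero-drop
#' convention: `V` is the sum of positive signed ranks; the p-value is exact
#' for small samples without ties and a normal approximation otherwise.
#' Identical pairs everywhere give `V = 0`, `p = 1`.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return list: `V`, `p`, `n` (non-zero differences), `exact`.
#' @export
pairedWilcoxon <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  n <- sum(d != 0)
  if (n == 0L) {
    return(list(V = 0, p = 1, n = 0L, exact = TRUE))
  }
  ties <- any(duplicated(abs(d[d != 0])))
  exact <- n <= 25L && !ties
  wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = exact, correct = !exact))
  list(V = unname(wt$statistic), p = wt$p.value, n = n, exact = exact)
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided two-sample Wilcoxon rank-sum test via [stats::wilcox.test()],
#' midranks for ties; exact null distribution for small tie-free samples,
#' normal approximation with tie correction otherwise.
#'
#' @param x,y numeric vectors, non-empty.
#' @return list: `W`, `p`, `exact`.
#' @export
mannWhitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1L) {
    return(list(W = length(x) * length(y) / 2, p = 1, exact = FALSE))
  }
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y)) < 50L && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  list(W = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Regression of detection span on years detected
#'
#' Per sex, ordinary least squares of the detection span `y` (last minus
#' first detection year) on the number of years actually detected `x`. A
#' slope near 1 means individuals were detected in every year of their
#' tenure; a slope near 2 means they tended to skip alternate years. The
#' sexes' slopes are compared through the interaction term of the pooled
#' model `span ~ years * sex`.
#'
#' @param span numeric, per-individual detection span in years.
#' @param years numeric, per-individual count of detection years.
#' @param sex character vector of group labels; at least 3 individuals per
#'   group.
#' @return list: `bySex` data.frame (`sex`, `slope`, `intercept`, `F`,
#'   `df`, `p`, `adjR2`, `n`) and `slopeDifference` (interaction estimate,
#'   `p`).
#' @export
detectionSpanRegression <- function(span, years, sex) {
  stopifnot(length(span) == length(years), length(span) == length(sex))
  out <- lapply(split(seq_along(span), sex), function(idx) {
    if (length(idx) < 3L) stop("need >= 3 individuals per sex")
    m <- lm(span[idx] ~ years[idx])
    s <- summary(m)
    data.frame(
      sex = sex[idx][1],
      slope = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
      F = unname(s$fstatistic[1]), df = unname(s$fstatistic[3]),
      p = unname(pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
        lower.tail = FALSE
      )),
      adjR2 = s$adj.r.squared, n = length(idx), stringsAsFactors = FALSE
    )
  })
  bySex <- do.call(rbind, out)
  rownames(bySex) <- NULL
  slopeDiff <- list(estimate = NA_real_, p = NA_real_)
  if (length(unique(sex)) > 1L) {
    pooled <- lm(span ~ years * sex)
    cf <- summary(pooled)$coefficients
    inter <- grep(":", rownames(cf))
    if (length(inter)) {
      slopeDiff <- list(estimate = unname(cf[inter[1], 1]), p = unname(cf[inter[1], 4]))
    }
  }
  list(bySex = bySex, slopeDifference = slopeDiff)
}

#' Quarterly subsampling of a year-long survey
#'
#' Splits a continuous year of detection events into four consecutive
#' 3-month windows (each the length of a regular dry-season survey) and
#' reports, per quarter and sex, the number and proportion of the year's
#' detected individuals seen in that window. The denominator is everyone of
#' that sex detected at any point in the year, so the proportions measure
#' within-year detection consistency.
#'
#' @param events independence-filtered event data.frame covering about a
#'   year.
#' @param start `Date`, start of the year-long survey; defaults to the
#'   earliest event date.
#' @return data.frame: `quarter`, `sex`, `nDetected`, `nTotal`,
#'   `proportion`, `percent` (rounded to whole percent, the study's
#'   reporting convention).
#' @export
quarterlySubsample <- function(events, start = NULL) {
  if (!nrow(events)) stop("no events supplied")
  if (is.null(start)) start <- as.Date(min(events$timestamp))
  bounds <- seq(as.Date(start), by = "3 months", length.out = 5L)
  ev <- events[as.Date(events$timestamp) >= bounds[1] &
    as.Date(events$timestamp) < bounds[5], , drop = FALSE]
  sexOf <- tapply(ev$sex, ev$individual_id, function(s) s[1])
  totals <- table(factor(unname(sexOf), c("male", "female", "unknown")))
  out <- list()
  for (q in 1:4) {
    inQ <- as.Date(ev$timestamp) >= bounds[q] & as.Date(ev$timestamp) < bounds[q + 1]
    ids <- unique(ev$individual_id[inQ])
    det <- table(factor(unname(sexOf[ids]), c("male", "female", "unknown")))
    for (s in c("male", "female", "unknown")) {
      if (totals[[s]] == 0L) next
      prop <- det[[s]] / totals[[s]]
      out[[length(out) + 1L]] <- data.frame(
        quarter = q, sex = s, nDetected = det[[s]], nTotal = totals[[s]],
        proportion = prop, percent = round(100 * prop),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
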