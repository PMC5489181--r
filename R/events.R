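#' Read detection events from a delimited text file
#'
#' Detection events are the raw currency of a camera-trap study: one
#' time-stamped identification of one individual at one station. The expected
#' file is a CSV with a header; required columns are `individual_id`, `sex`,
#' `station_id` and `timestamp` (local time, `"YYYY-MM-DD HH:MM:SS"`); an
#' optional `age_class` column (`adult`/`cub`) defaults to `adult`. Column
#' names can be remapped through `schema`.
#'
#' Rows whose timestamp cannot be parsed are dropped; their row numbers are
#' reported in the `"rejected"` attribute of the result and through a
#' warning.
#'
#' @param path file to read.
#' @param schema named character vector mapping the canonical column names to
#'   the file's column names, e.g. `c(individual_id = "ID")`.
#' @return data.frame of events with columns `individual_id`, `sex`,
#'   `age_class`, `station_id`, `timestamp` (`POSIXct`), sorted by individual
#'   then time, with attribute `rejected` holding the data row numbers of
#'   unparseable timestamps.
#' @export
parseEvents <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("individual_id", "sex", "station_id", "timestamp")
  cols <- setNames(c(required, "age_class"), c(required, "age_class"))
  if (!is.null(schema)) cols[names(schema)] <- schema
  for (cc in required) {
    if (!cols[[cc]] %in% names(raw)) {
      stop(sprintf("required column '%s' is missing", cols[[cc]]))
    }
  }
  if (nrow(raw) == 0L) stop("no event rows in ", path)
  ts <- .parseTimestamp(raw[[cols[["timestamp"]]]])
  rejected <- which(is.na(ts))
  if (length(rejected)) {
    warning(sprintf(
      "%d row(s) rejected for unparseable timestamps: %s",
      length(rejected), paste(rejected, collapse = ", ")
    ))
  }
  keep <- !is.na(ts)
  events <- data.frame(
    individual_id = raw[[cols[["individual_id"]]]][keep],
    sex = .normaliseSex(raw[[cols[["sex"]]]][keep]),
    age_class = if (cols[["age_class"]] %in% names(raw)) {
      ifelse(raw[[cols[["age_class"]]]][keep] %in% c("adult", "cub"),
        raw[[cols[["age_class"]]]][keep], "adult"
      )
    } else {
      "adult"
    },
    station_id = raw[[cols[["station_id"]]]][keep],
    timestamp = ts[keep],
    stringsAsFactors = FALSE
  )
  events <- events[order(events$individual_id, events$timestamp), , drop = FALSE]
  rownames(events) <- NULL
  attr(events, "rejected") <- rejected
  events
}

.parseTimestamp <- function(x) {
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  alt <- is.na(out)
  if (any(alt)) {
    out[alt] <- as.POSIXct(x[alt], tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  }
  out
}

.normaliseSex <- function(x) {
  x <- tolower(trimws(x))
  x[x %in% c("m")] <- "male"
  x[x %in% c("f")] <- "female"
  x[!x %in% c("male", "female")] <- "unknown"
  x
}

#' Filter events to temporal independence
#'
#' Consecutive photographs of the same individual minutes apart are not
#' independent samples. Per individual, a greedy forward scan keeps an event
#' only if it falls at least `minGapHours` after the last *kept* event of
#' that individual; the first event of each individual is always kept.
#' Different individuals never interact. The default 24-hour gap is the
#' standard camera-trap independence rule.
#'
#' The scan is idempotent: filtering an already-filtered set changes nothing.
#'
#' @param events event data.frame (see [parseEvents()]).
#' @param minGapHours minimum gap between kept events, in hours; must be
#'   non-negative.
#' @return the filtered event data.frame, same columns, sorted by individual
#'   and time.
#' @export
filterIndependent <- function(events, minGapHours = 24) {
  if (!is.numeric(minGapHours) || minGapHours < 0) {
    stop("minGapHours must be non-negative")
  }
  if (nrow(events) == 0L) {
    return(events)
  }
  events <- events[order(events$individual_id, events$timestamp), , drop = FALSE]
  gap <- minGapHours * 3600
  keep <- logical(nrow(events))
  tnum <- as.numeric(events$timestamp)
  for (idx in split(seq_len(nrow(events)), events$individual_id)) {
    last <- -Inf
    for (i in idx) {
      if (tnum[i] - last >= gap) {
        keep[i] <- TRUE
        last <- tnum[i]
      }
    }
  }
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- attr(events, "rejected")
  out
}

#' Write detection events to CSV
#'
#' Inverse of [parseEvents()]: the written file round-trips through
#' [parseEvents()] to an identical event table.
#'
#' @param events event data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeEvents <- function(events, path) {
  out <- events
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
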