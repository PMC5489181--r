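#' Export capture histories as a MARK-style encounter file
#'
#' One line per individual: the concatenated 0/1 string over all secondary
#' occasions in primary order, then one frequency column per sex group
#' (male, female, plus unknown when present), terminated by `;`. The header
#' comment records the secondary-occasion block sizes, and each line carries
#' the individual id as a trailing comment so the text round-trips through
#' [readMarkInp()] without loss.
#'
#' @param ch a [CaptureHistory-class].
#' @param file optional path; when given the text is also written there.
#' @return the encounter text as a character vector of lines, invisibly when
#'   `file` is given.
#' @export
exportMarkInp <- function(ch, file = NULL) {
  validObject(ch)
  groups <- c("male", "female")
  if (any(ch@individuals$sex == "unknown")) groups <- c(groups, "unknown")
  header <- c(
    sprintf(
      "/* robust design encounter histories; occasions per primary: %s */",
      paste(ch@design@nSecondary, collapse = " ")
    ),
    sprintf("/* groups: %s */", paste(groups, collapse = " "))
  )
  lines <- character(nrow(ch@sec))
  for (i in seq_len(nrow(ch@sec))) {
    freq <- as.integer(groups == ch@individuals$sex[i])
    lines[i] <- sprintf(
      "%s %s; /* %s */",
      paste(ch@sec[i, ], collapse = ""),
      paste(freq, collapse = " "),
      ch@individuals$id[i]
    )
  }
  out <- c(header, lines)
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Read a MARK-style encounter file back into a CaptureHistory
#'
#' Inverse of [exportMarkInp()] for files written by it (group labels taken
#' from the header comment, individual ids from the trailing comments when
#' present).
#'
#' @param lines character vector of lines, or a file path.
#' @param design the [SurveyDesign-class] the occasions refer to.
#' @return a [CaptureHistory-class].
#' @export
readMarkInp <- function(lines, design) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  groupLine <- grep("/\\* groups:", lines, value = TRUE)
  groups <- if (length(groupLine)) {
    strsplit(sub(".*groups: *", "", sub(" *\\*/", "", groupLine[1])), " +")[[1]]
  } else {
    c("male", "female")
  }
  body <- lines[!grepl("^/\\*", lines) & nzchar(trimws(lines))]
  n <- length(body)
  nOcc <- sum(design@nSecondary)
  mat <- matrix(0L, n, nOcc)
  sex <- character(n)
  ids <- sprintf("ind%03d", seq_len(n))
  for (i in seq_len(n)) {
    ln <- body[i]
    cm <- regmatches(ln, regexpr("/\\*.*\\*/", ln))
    if (length(cm)) ids[i] <- trimws(gsub("/\\*|\\*/", "", cm))
    ln <- trimws(sub(";.*", "", ln))
    parts <- strsplit(ln, " +")[[1]]
    hist <- parts[1]
    if (nchar(hist) != nOcc) {
      stop(sprintf(
        "line %d: history has %d occasions, design expects %d",
        i, nchar(hist), nOcc
      ))
    }
    mat[i, ] <- as.integer(strsplit(hist, "")[[1]])
    freq <- as.integer(parts[-1])
    sex[i] <- groups[which(freq != 0)[1]]
  }
  K <- design@nSecondary
  colnames(mat) <- unlist(lapply(
    seq_along(K),
    function(j) sprintf("%d.%d", design@years[j], seq_len(K[j]))
  ))
  rownames(mat) <- ids
  new("CaptureHistory",
    individuals = data.frame(id = ids, sex = sex, stringsAsFactors = FALSE),
    sec = mat, design = design, report = list(source = "mark-inp")
  )
}
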