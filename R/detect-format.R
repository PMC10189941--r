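#' Detect the format of a sequence-related file
#'
#' Pure content-based detection (no extension sniffing): SQLite magic bytes
#' mean SQPD (confirmed against the SQPD schema), a leading `# PEFF` comment
#' means PEFF, a leading `>` means FASTA, a JSON object carrying the SET
#' signature key means SET, and a file whose every non-blank line is an
#' amino-acid string is a peptide list. Recoverable problems (duplicate
#' accessions, illegal residues, empty records) are reported in the issue
#' list without failing detection.
#'
#' @param path Path to an existing, non-empty file.
#' @return `list(format = <string>, issues = <character vector>)` where
#'   format is one of `fasta`, `peff`, `sqpd`, `set`, `peptide_list`,
#'   `unknown`.
#' @export
detect_format <- function(path) {
  if (!file.exists(path) || dir.exists(path))
    sdk_stop("file_unreadable", paste("no such file:", path))
  size <- file.info(path)$size
  if (is.na(size) || size == 0L)
    sdk_stop("file_unreadable", paste("file is empty:", path))

  magic <- readBin(path, "raw", n = 16L)
  if (length(magic) >= 16L && rawToChar(magic[1:15]) == "SQLite format 3") {
    issues <- character()
    ok <- tryCatch({
      h <- open_sqpd(path)
      on.exit(close_sqpd(h), add = TRUE)
      TRUE
    }, error = function(e) {
      issues <<- conditionMessage(e)
      FALSE
    })
    if (ok) return(list(format = "sqpd", issues = issues))
    return(list(format = "unknown",
                issues = c("SQLite file without the SQPD schema", issues)))
  }

  lines <- tryCatch(sub("\r$", "", readLines(path, warn = FALSE)),
                    error = function(e) sdk_stop("file_unreadable", conditionMessage(e)))
  nonblank <- trimws(lines[nzchar(trimws(lines))])
  if (!length(nonblank)) sdk_stop("file_unreadable", paste("file is blank:", path))

  if (grepl("^# *PEFF", nonblank[1])) {
    issues <- tryCatch({ read_peff(path); character() },
                       error = function(e) conditionMessage(e))
    return(list(format = "peff", issues = issues))
  }

  if (startsWith(nonblank[1], ">")) {
    return(list(format = "fasta", issues = .fasta_issues(lines)))
  }

  json <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                   error = function(e) NULL)
  if (is.list(json)) {
    if (identical(json[["format"]], "SET")) {
      issues <- tryCatch({ read_set(path); character() },
                         error = function(e) conditionMessage(e))
      return(list(format = "set", issues = issues))
    }
    return(list(format = "unknown", issues = "JSON without the SET signature key"))
  }

  peptideish <- vapply(nonblank, function(x) grepl("^[A-Za-z]+$", sub("#.*$", "", x)) ||
                         startsWith(x, "#"), logical(1))
  if (all(peptideish)) {
    issues <- character()
    for (p in nonblank[!startsWith(nonblank, "#")]) {
      bad <- tryCatch({ validate_sequence(p, "AA"); NULL },
                      error = function(e) conditionMessage(e))
      if (!is.null(bad)) issues <- c(issues, paste0("'", p, "': ", bad))
    }
    if (!length(issues)) return(list(format = "peptide_list", issues = issues))
  }

  list(format = "unknown", issues = character())
}

# tolerant FASTA scan collecting recoverable problems
.fasta_issues <- function(lines) {
  issues <- character()
  seen <- character()
  acc <- NULL; nseq <- 0L
  for (line in lines) {
    line <- trimws(line)
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      if (!is.null(acc) && nseq == 0L)
        issues <- c(issues, paste("empty record:", acc))
      acc <- tryCatch(parse_header(line)$accession, error = function(e) "?")
      if (acc %in% seen) issues <- c(issues, paste("duplicate accession", acc))
      seen <- c(seen, acc)
      nseq <- 0L
    } else {
      nseq <- nseq + nchar(line)
      bad <- tryCatch({ validate_sequence(line, "AA"); NULL },
                      error = function(e) e)
      if (!is.null(bad) && inherits(bad, "seqdbkit_illegal_character"))
        issues <- c(issues, paste0("illegal residue '", bad$char, "' in ", acc %||% "?"))
    }
  }
  if (!is.null(acc) && nseq == 0L) issues <- c(issues, paste("empty record:", acc))
  unique(issues)
}
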