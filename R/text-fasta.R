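#' Read a FASTA file
#'
#' Reads protein (or nucleotide) FASTA into a list of entries. The reader
#' tolerates CRLF line endings, blank lines and trailing whitespace. Headers
#' are parsed with [parse_header()] under the requested dialect.
#'
#' @param path Path to a FASTA file.
#' @param dialect Header dialect passed to [parse_header()].
#' @param alphabet `"AA"` (returns [protein_entry()] objects) or `"NA"`
#'   (returns plain records with `accession`, `description`, `sequence`).
#' @param on_duplicate Policy when the same accession occurs twice:
#'   `"error"` (default), `"skip"` (keep the first) or `"suffix"` (append
#'   `_2`, `_3`, ...).
#' @return A list of entries.
#' @export
read_fasta <- function(path, dialect = "auto", alphabet = c("AA", "NA"),
                       on_duplicate = c("error", "skip", "suffix")) {
  alphabet <- match.arg(alphabet)
  on_duplicate <- match.arg(on_duplicate)
  if (!file.exists(path)) sdk_stop("file_unreadable", paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  nonblank <- lines[nzchar(trimws(lines))]
  if (!length(nonblank) || !startsWith(trimws(nonblank[1]), ">"))
    sdk_stop("not_fasta", paste(path, "does not look like FASTA (no leading '>')"))

  entries <- list()
  seen <- new.env(parent = emptyenv())
  header <- NULL
  chunks <- character()

  flush <- function(header, chunks) {
    seq <- paste(chunks, collapse = "")
    parsed <- parse_header(header, dialect)
    if (!nzchar(gsub("[[:space:]]", "", seq)))
      sdk_stop("empty_record", sprintf("record '%s' has no sequence", parsed$accession))
    acc <- parsed$accession
    if (!is.null(seen[[acc]])) {
      if (on_duplicate == "error")
        sdk_stop("duplicate_accession", paste("duplicate accession:", acc))
      if (on_duplicate == "skip") return(NULL)
      k <- seen[[acc]] + 1L
      seen[[acc]] <- k
      acc <- paste0(acc, "_", k)
    } else {
      seen[[parsed$accession]] <- 1L
    }
    if (alphabet == "AA") {
      protein_entry(acc, seq, description = parsed$description,
                    prefix = parsed$prefix, meta = parsed$meta)
    } else {
      list(accession = acc, description = parsed$description,
           sequence = validate_sequence(seq, "NA"))
    }
  }

  for (line in lines) {
    line <- sub("[[:space:]]+$", "", line)
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      if (!is.null(header)) {
        e <- flush(header, chunks)
        if (!is.null(e)) entries[[length(entries) + 1L]] <- e
      }
      header <- line
      chunks <- character()
    } else {
      if (is.null(header)) sdk_stop("not_fasta", "sequence data before first header")
      chunks <- c(chunks, gsub("[[:space:]]", "", line))
    }
  }
  if (!is.null(header)) {
    e <- flush(header, chunks)
    if (!is.null(e)) entries[[length(entries) + 1L]] <- e
  }
  entries
}

#' Write entries to a FASTA file
#'
#' @param entries List of [protein_entry()] objects (or plain records with
#'   `accession`/`description`/`sequence`).
#' @param path Output path.
#' @param wrap Sequence line width; `0` writes each sequence on one line.
#'   Default 60.
#' @param dialect Header dialect for [compose_header()].
#' @return `path`, invisibly.
#' @export
write_fasta <- function(entries, path, wrap = 60L, dialect = "generic") {
  if (wrap < 0L) sdk_stop("invalid_argument", "wrap must be >= 0")
  con <- file(path, "w")
  on.exit(close(con))
  for (e in entries) {
    hdr <- if (inherits(e, "protein_entry")) compose_header(e, dialect)
           else if (nzchar(e$description %||% "")) paste0(">", e$accession, " ", e$description)
           else paste0(">", e$accession)
    writeLines(hdr, con)
    writeLines(wrap_sequence(e$sequence, wrap), con)
  }
  invisible(path)
}

wrap_sequence <- function(seq, wrap) {
  if (wrap == 0L || nchar(seq) <= wrap) return(seq)
  starts <- seq.int(1L, nchar(seq), by = wrap)
  substring(seq, starts, pmin(starts + wrap - 1L, nchar(seq)))
}

#' Read a plain-text peptide list
#'
#' One peptide per line; blank lines and `#` comments are ignored; every
#' peptide is validated against the amino-acid alphabet.
#'
#' @param path Path to the list file.
#' @return Character vector of peptide sequences.
#' @export
read_peptide_list <- function(path) {
  if (!file.exists(path)) sdk_stop("file_unreadable", paste("no such file:", path))
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  vapply(lines, validate_sequence, character(1), alphabet = "AA", USE.NAMES = FALSE)
}
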