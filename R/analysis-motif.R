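# Motif grammar: amino-acid letters, 'x' (any residue) and bracket classes
# like "[ST]". "NxS" matches Asn, anything, Ser. Occurrences are counted
# with full overlap (every start position is tested).

motif_to_regex <- function(pattern) {
  if (!is_string(pattern) || !nzchar(pattern))
    sdk_stop("bad_pattern", "empty motif pattern")
  out <- character()
  i <- 1L; n <- nchar(pattern)
  while (i <= n) {
    ch <- substr(pattern, i, i)
    if (ch == "[") {
      close_at <- regexpr("]", substr(pattern, i, n), fixed = TRUE)
      if (close_at == -1L)
        sdk_stop("bad_pattern", paste("unbalanced bracket in motif:", pattern))
      inner <- substr(pattern, i + 1L, i + close_at - 2L)
      if (!nzchar(inner) || !grepl("^[A-Za-z]+$", inner))
        sdk_stop("bad_pattern", paste("bad bracket class in motif:", pattern))
      out <- c(out, paste0("[", toupper(inner), "]"))
      i <- i + close_at
    } else if (ch %in% c("x", "X", ".")) {
      out <- c(out, "."); i <- i + 1L
    } else if (grepl("^[A-Za-z]$", ch)) {
      out <- c(out, toupper(ch)); i <- i + 1L
    } else {
      sdk_stop("bad_pattern", sprintf("illegal character '%s' in motif '%s'", ch, pattern))
    }
  }
  paste(out, collapse = "")
}

#' Count motif occurrences in a sequence
#'
#' Counts overlapping matches of each motif: a lookahead scan tests every
#' start position, so `"AA"` occurs three times in `"AAAA"`.
#'
#' @param entry A [protein_entry()] or sequence string.
#' @param motifs Character vector of motif patterns (letters, `x` wildcard,
#'   `[..]` classes).
#' @return Named integer vector, motif -> count.
#' @export
#' @examples
#' count_motifs("NASNGS", "Nx[ST]")  # 2
count_motifs <- function(entry, motifs) {
  seq <- if (is.character(entry)) validate_sequence(entry, "AA") else entry$sequence
  counts <- vapply(motifs, function(m) {
    rx <- paste0("(?=", motif_to_regex(m), ")")
    hits <- gregexpr(rx, seq, perl = TRUE)[[1]]
    if (hits[1] == -1L) 0L else length(hits)
  }, integer(1))
  stats::setNames(counts, motifs)
}

#' Extract residue windows around sites or peptides
#'
#' Site queries extract a window of exactly `2*flank + 1` residues centered
#' on the 1-based site, padded with `pad` beyond the termini. Peptide
#' queries locate the peptide by exact substring search and center the
#' window on the first residue of every occurrence; peptides that cannot
#' be located are reported with an empty window and a warning.
#'
#' @param source An open `sqpd_handle`, a list of [protein_entry()]
#'   objects, or one [protein_entry()].
#' @param queries Either a data.frame/list with `accession` and `site`
#'   columns, or a character vector of peptide sequences.
#' @param flank Number of residues on each side (>= 1).
#' @param pad Padding character beyond the termini (default `"-"`).
#' @return A data.frame with columns `query`, `accession`, `center`,
#'   `window`.
#' @export
sequence_windows <- function(source, queries, flank = 7L, pad = "-") {
  if (flank < 1L) sdk_stop("invalid_argument", "flank must be >= 1")
  if (nchar(pad) != 1L) sdk_stop("invalid_argument", "pad must be one character")

  get_seq <- function(acc) {
    if (inherits(source, "sqpd_handle")) return(get_entry(source, acc)$sequence)
    entries <- if (inherits(source, "protein_entry")) list(source) else source
    for (e in entries) if (e$accession == acc) return(e$sequence)
    sdk_stop("accession_not_found", paste("no entry with accession", acc))
  }
  all_entries <- function() {
    if (inherits(source, "sqpd_handle")) return(get_entries(source))
    if (inherits(source, "protein_entry")) list(source) else source
  }

  cut_window <- function(seq, site) {
    n <- nchar(seq)
    if (site < 1L || site > n)
      sdk_stop("site_out_of_range", sprintf("site %d outside 1..%d", site, n))
    idx <- (site - flank):(site + flank)
    chars <- ifelse(idx >= 1L & idx <= n,
                    strsplit(seq, "")[[1]][pmax(pmin(idx, n), 1L)], pad)
    paste(chars, collapse = "")
  }

  rows <- list()
  if (is.character(queries)) {
    entries <- all_entries()
    for (pep in queries) {
      pep_n <- validate_sequence(pep, "AA")
      found <- FALSE
      for (e in entries) {
        hits <- gregexpr(pep_n, e$sequence, fixed = TRUE)[[1]]
        if (hits[1] == -1L) next
        for (h in hits) {
          found <- TRUE
          rows[[length(rows) + 1L]] <- data.frame(
            query = pep, accession = e$accession, center = h,
            window = cut_window(e$sequence, h), stringsAsFactors = FALSE)
        }
      }
      if (!found) {
        sdk_warn("peptide_not_found", paste("peptide not located:", pep))
        rows[[length(rows) + 1L]] <- data.frame(
          query = pep, accession = NA_character_, center = NA_integer_,
          window = "", stringsAsFactors = FALSE)
      }
    }
  } else {
    q <- as.data.frame(queries, stringsAsFactors = FALSE)
    if (!all(c("accession", "site") %in% names(q)))
      sdk_stop("invalid_argument", "site queries need 'accession' and 'site'")
    for (i in seq_len(nrow(q))) {
      seq <- get_seq(q$accession[i])
      site <- as.integer(q$site[i])
      rows[[length(rows) + 1L]] <- data.frame(
        query = sprintf("%s@%d", q$accession[i], site),
        accession = q$accession[i], center = site,
        window = cut_window(seq, site), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
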