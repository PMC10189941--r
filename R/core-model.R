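#' Construct a proteoform feature
#'
#' A feature is one proteoform annotation on a protein sequence: a controlled
#' kind, a 1-based inclusive residue range and an optional payload (the
#' replacement residue of a variant, or a modification name).
#'
#' @param kind One of `SIGNAL`, `CHAIN`, `PROPEP`, `TRANSIT`, `INIT_MET`,
#'   `VARIANT`, `MOD_RES`, `CONFLICT`.
#' @param start,end 1-based inclusive residue positions, `start <= end`.
#' @param payload Free-text payload; for a single-residue variant this is the
#'   replacement residue.
#' @param source_key Original key in the source annotation (e.g. the UniProt
#'   column label), kept for provenance.
#' @return An object of class `seq_feature`.
#' @export
feature <- function(kind, start, end = start, payload = "", source_key = kind) {
  kind <- match.arg(kind, FEATURE_KINDS)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end)
    sdk_stop("invalid_feature", sprintf("feature %s has invalid range %s..%s", kind, start, end))
  structure(
    list(kind = kind, start = start, end = end,
         payload = as.character(payload), source_key = as.character(source_key)),
    class = "seq_feature"
  )
}

#' @export
format.seq_feature <- function(x, ...) {
  sprintf("%s %d..%d%s", x$kind, x$start, x$end,
          if (nzchar(x$payload)) paste0(" [", x$payload, "]") else "")
}

#' @export
print.seq_feature <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Construct a protein database entry
#'
#' The central record type: one protein with its accession, header metadata,
#' residue sequence and proteoform features.
#'
#' @param accession Unique, non-empty accession string.
#' @param sequence Amino-acid sequence; validated and upper-cased with
#'   [validate_sequence()].
#' @param description Free-text description (the header text after the
#'   accession).
#' @param prefix Source tag, e.g. `"sp"`, `"tr"` or `"generic"`.
#' @param features List of [feature()] objects; every range must lie within
#'   the sequence.
#' @param meta Named character vector/list of header key-values (`GN`, `OS`,
#'   `OX`, `PE`, `SV`, ...).
#' @return An object of class `protein_entry`.
#' @export
protein_entry <- function(accession, sequence, description = "",
                          prefix = "generic", features = list(), meta = character()) {
  if (!is_string(accession) || !nzchar(accession))
    sdk_stop("invalid_accession", "accession must be a non-empty string")
  sequence <- validate_sequence(sequence, "AA")
  len <- nchar(sequence)
  features <- lapply(features, function(f) {
    if (!inherits(f, "seq_feature")) sdk_stop("invalid_feature", "features must be seq_feature objects")
    if (f$end > len)
      sdk_stop("feature_out_of_range",
               sprintf("feature %s %d..%d exceeds sequence length %d of %s",
                       f$kind, f$start, f$end, len, accession))
    f
  })
  meta <- as.list(meta)
  if (length(meta) && (is.null(names(meta)) || any(!nzchar(names(meta)))))
    sdk_stop("invalid_meta", "meta must be fully named")
  structure(
    list(accession = accession, prefix = prefix, description = description,
         sequence = sequence, features = features,
         meta = lapply(meta, as.character)),
    class = "protein_entry"
  )
}

#' @export
format.protein_entry <- function(x, ...) {
  sprintf("<protein_entry %s: %d aa, %d feature(s)>",
          x$accession, nchar(x$sequence), length(x$features))
}

#' @export
print.protein_entry <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Database-level metadata
#'
#' Identity and bookkeeping for one sequence database: name, version, source,
#' sequence type and entry count, plus a free `extra` map that carries PEFF
#' file-header keys through conversions.
#'
#' @param db_name,db_version Non-empty identity strings.
#' @param db_source One of `uniprot`, `ncbi`, `ensembl`, `custom`.
#' @param sequence_type `"AA"` or `"NA"`.
#' @param n_entries Non-negative entry count.
#' @param created ISO-8601 timestamp; defaults to now (UTC).
#' @param extra Named list of pass-through key-values.
#' @return An object of class `database_meta`.
#' @export
database_meta <- function(db_name, db_version = "1",
                          db_source = c("custom", "uniprot", "ncbi", "ensembl"),
                          sequence_type = c("AA", "NA"),
                          n_entries = 0L, created = iso_now(), extra = list()) {
  if (!is_string(db_name) || !nzchar(db_name))
    sdk_stop("invalid_meta", "db_name must be a non-empty string")
  if (!is_string(db_version) || !nzchar(db_version))
    sdk_stop("invalid_meta", "db_version must be a non-empty string")
  structure(
    list(db_name = db_name, db_version = db_version,
         db_source = match.arg(db_source), sequence_type = match.arg(sequence_type),
         n_entries = as.integer(n_entries), created = created,
         extra = lapply(as.list(extra), as.character)),
    class = "database_meta"
  )
}

#' Validate and normalize a residue sequence
#'
#' Upper-cases the sequence and checks it against the chosen alphabet. The
#' amino-acid alphabet is the 20 standard residues plus the ambiguity/rare
#' letters B, Z, X, U, O, J; the nucleotide alphabet is A, C, G, T, N with
#' RNA `U` normalized to `T`.
#'
#' @param seq A single sequence string; surrounding whitespace is stripped.
#' @param alphabet `"AA"` (default) or `"NA"`.
#' @return The normalized (upper-case) sequence string.
#' @export
#' @examples
#' validate_sequence("acdef")          # "ACDEF"
#' validate_sequence("augc", "NA")     # "ATGC"
validate_sequence <- function(seq, alphabet = c("AA", "NA")) {
  alphabet <- match.arg(alphabet)
  if (!is_string(seq)) sdk_stop("empty_sequence", "sequence must be a single string")
  seq <- toupper(gsub("[[:space:]]+", "", seq))
  if (!nzchar(seq)) sdk_stop("empty_sequence", "sequence is empty")
  if (alphabet == "NA") seq <- gsub("U", "T", seq, fixed = TRUE)
  allowed <- if (alphabet == "AA") AA_EXTENDED else NA_ALPHABET
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% allowed)
  if (length(bad)) {
    sdk_stop("illegal_character",
             sprintf("illegal character '%s' at position %d for alphabet %s",
                     chars[bad[1]], bad[1], alphabet),
             char = chars[bad[1]], position = bad[1])
  }
  seq
}

# --- FASTA header grammars ---------------------------------------------------

# UniProt: >db|ACCESSION|ENTRY_NAME Description OS=... OX=... GN=... PE=... SV=...
.parse_header_uniprot <- function(line) {
  m <- regmatches(line, regexec("^>(sp|tr)\\|([^| ]+)\\|(\\S+)(.*)$", line))[[1]]
  if (!length(m)) return(NULL)
  rest <- trimws(m[5])
  meta <- list(entry_name = m[4])
  desc <- rest
  # split off trailing KEY=value tags (OS may contain spaces, so scan keys)
  tagpat <- "\\b(OS|OX|GN|PE|SV)=" # nolint
  starts <- gregexpr(tagpat, rest)[[1]]
  if (starts[1] != -1L) {
    desc <- trimws(substr(rest, 1L, starts[1] - 1L))
    bounds <- c(starts, nchar(rest) + 1L)
    for (i in seq_along(starts)) {
      piece <- trimws(substr(rest, bounds[i], bounds[i + 1L] - 1L))
      key <- sub("=.*$", "", piece)
      meta[[key]] <- sub("^[A-Z]+=", "", piece)
    }
  }
  list(prefix = m[2], accession = m[3], description = desc, meta = meta)
}

# NCBI: >ACC.V description   (versioned accession token)
.parse_header_ncbi <- function(line) {
  m <- regmatches(line, regexec("^>([A-Za-z]{2}_?[A-Za-z0-9]+\\.[0-9]+)\\s*(.*)$", line))[[1]]
  if (!length(m)) return(NULL)
  list(prefix = "ncbi", accession = m[2], description = trimws(m[3]), meta = list())
}

# Ensembl: >ENSP... pep description-ish fields
.parse_header_ensembl <- function(line) {
  m <- regmatches(line, regexec("^>(ENS[A-Z]*[PTG][0-9]{6,})(?:\\.[0-9]+)?\\s*(.*)$", line))[[1]]
  if (!length(m)) return(NULL)
  list(prefix = "ensembl", accession = m[2], description = trimws(m[3]), meta = list())
}

.parse_header_generic <- function(line) {
  body <- sub("^>", "", line)
  body <- trimws(body)
  if (!nzchar(body)) return(NULL)
  acc <- sub("\\s.*$", "", body)
  desc <- if (acc == body) "" else trimws(substr(body, nchar(acc) + 1L, nchar(body)))
  list(prefix = "generic", accession = acc, description = desc, meta = list())
}

#' Parse a FASTA header line
#'
#' Supports the UniProt (`>sp|ACC|NAME ... OS= OX= GN= PE= SV=`), NCBI
#' (`>ACC.V description`), Ensembl and generic (first token = accession)
#' header dialects. With `dialect = "auto"` the grammars are tried in the
#' order uniprot, ncbi, ensembl, generic and the first match wins.
#'
#' @param line A header line starting with `>`.
#' @param dialect One of `auto`, `uniprot`, `ncbi`, `ensembl`, `generic`.
#' @return A list with `prefix`, `accession`, `description` and `meta` (named
#'   list of header tags).
#' @export
#' @examples
#' parse_header(">sp|P00001|TEST_MOUSE Test protein OS=Mus musculus OX=10090 GN=Tst PE=1 SV=2")
parse_header <- function(line, dialect = c("auto", "uniprot", "ncbi", "ensembl", "generic")) {
  dialect <- match.arg(dialect)
  if (!is_string(line) || !startsWith(line, ">"))
    sdk_stop("malformed_header", "header line must start with '>'")
  line <- sub("[[:space:]]+$", "", line)
  if (line == ">")
    sdk_stop("malformed_header", "header line is '>' with no content")
  parsers <- switch(dialect,
    auto = list(.parse_header_uniprot, .parse_header_ncbi,
                .parse_header_ensembl, .parse_header_generic),
    uniprot = list(.parse_header_uniprot),
    ncbi = list(.parse_header_ncbi),
    ensembl = list(.parse_header_ensembl),
    generic = list(.parse_header_generic)
  )
  for (p in parsers) {
    out <- p(line)
    if (!is.null(out)) return(out)
  }
  sdk_stop("malformed_header",
           sprintf("header does not match the %s grammar: %s", dialect, line))
}

#' Compose a FASTA header line
#'
#' Inverse of [parse_header()] on the modeled fields: for every supported
#' dialect, parsing a composed header recovers the entry's accession, prefix
#' and meta tags.
#'
#' @param entry A [protein_entry()].
#' @param dialect `"uniprot"` or `"generic"`.
#' @return A single header string starting with `>`.
#' @export
compose_header <- function(entry, dialect = c("generic", "uniprot")) {
  dialect <- match.arg(dialect)
  if (dialect == "uniprot") {
    prefix <- if (entry$prefix %in% c("sp", "tr")) entry$prefix else "sp"
    name <- entry$meta[["entry_name"]] %||% paste0(entry$accession, "_X")
    parts <- paste0(">", prefix, "|", entry$accession, "|", name)
    if (nzchar(entry$description)) parts <- paste(parts, entry$description)
    for (key in c("OS", "OX", "GN", "PE", "SV")) {
      if (!is.null(entry$meta[[key]]))
        parts <- paste0(parts, " ", key, "=", entry$meta[[key]])
    }
    parts
  } else {
    if (nzchar(entry$description)) paste0(">", entry$accession, " ", entry$description)
    else paste0(">", entry$accession)
  }
}
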