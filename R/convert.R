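# One-call format conversions composing the format modules. These are the
# library surface behind the conversion tools.

#' Convert FASTA (plus optional annotation table) to SQPD
#'
#' @param fasta_path Input FASTA.
#' @param sqpd_path Output SQPD file.
#' @param db_name,db_version,db_source Database identity; `db_name`
#'   defaults to the FASTA file name.
#' @param table_path Optional UniProt-style annotation table supplying
#'   proteoform features; without it the database is featureless.
#' @param on_duplicate Duplicate-accession policy.
#' @param overwrite Replace an existing output file.
#' @return Number of entries written, invisibly.
#' @export
fasta_to_sqpd <- function(fasta_path, sqpd_path,
                          db_name = NULL, db_version = "1", db_source = "custom",
                          table_path = NULL, on_duplicate = "error",
                          overwrite = FALSE) {
  entries <- read_fasta(fasta_path, on_duplicate = on_duplicate)
  if (!is.null(table_path))
    entries <- apply_feature_table(entries, read_annotation_table(table_path))
  meta <- database_meta(db_name %||% basename(fasta_path), db_version,
                        db_source = db_source)
  h <- create_sqpd(sqpd_path, meta, overwrite = overwrite)
  on.exit(close_sqpd(h))
  add_entries(h, entries, on_duplicate = on_duplicate)
  invisible(length(entries))
}

#' Convert SQPD to FASTA
#' @param sqpd_path Input SQPD; `fasta_path` output FASTA.
#' @param wrap,dialect Passed to [write_fasta()].
#' @return Number of entries written, invisibly.
#' @export
sqpd_to_fasta <- function(sqpd_path, fasta_path, wrap = 60L, dialect = "generic") {
  h <- open_sqpd(sqpd_path)
  on.exit(close_sqpd(h))
  entries <- get_entries(h)
  write_fasta(entries, fasta_path, wrap = wrap, dialect = dialect)
  invisible(length(entries))
}

#' Convert SQPD to PEFF
#' @param sqpd_path Input SQPD; `peff_path` output PEFF file.
#' @return Number of entries written, invisibly.
#' @export
sqpd_to_peff <- function(sqpd_path, peff_path) {
  h <- open_sqpd(sqpd_path)
  on.exit(close_sqpd(h))
  entries <- get_entries(h)
  write_peff(sqpd_meta(h), entries, peff_path)
  invisible(length(entries))
}

#' Convert PEFF to SQPD
#' @param peff_path Input PEFF; `sqpd_path` output SQPD.
#' @param overwrite Replace an existing output file.
#' @return Number of entries written, invisibly.
#' @export
peff_to_sqpd <- function(peff_path, sqpd_path, overwrite = FALSE) {
  peff <- read_peff(peff_path)
  h <- create_sqpd(sqpd_path, peff$meta, overwrite = overwrite)
  on.exit(close_sqpd(h))
  add_entries(h, peff$entries)
  invisible(length(peff$entries))
}

#' Convert FASTA to PEFF
#' @inheritParams fasta_to_sqpd
#' @param peff_path Output PEFF file.
#' @return Number of entries written, invisibly.
#' @export
fasta_to_peff <- function(fasta_path, peff_path,
                          db_name = NULL, db_version = "1", db_source = "custom",
                          table_path = NULL) {
  entries <- read_fasta(fasta_path)
  if (!is.null(table_path))
    entries <- apply_feature_table(entries, read_annotation_table(table_path))
  meta <- database_meta(db_name %||% basename(fasta_path), db_version,
                        db_source = db_source, n_entries = length(entries))
  write_peff(meta, entries, peff_path)
  invisible(length(entries))
}

#' Convert PEFF to FASTA (headers lose the tag block)
#' @param peff_path Input PEFF; `fasta_path` output FASTA.
#' @param wrap Sequence wrap width.
#' @return Number of entries written, invisibly.
#' @export
peff_to_fasta <- function(peff_path, fasta_path, wrap = 60L) {
  peff <- read_peff(peff_path)
  write_fasta(peff$entries, fasta_path, wrap = wrap)
  invisible(length(peff$entries))
}

#' Materialize a SET as FASTA
#'
#' The tutorial path: resolve the SET against its parent SQPD and write the
#' named subset, in SET order, as classic FASTA.
#'
#' @param set_path Input SET file.
#' @param sqpd_path Parent SQPD database.
#' @param fasta_path Output FASTA.
#' @param on_missing Passed to [resolve_set()].
#' @return Number of entries written, invisibly.
#' @export
set_to_fasta <- function(set_path, sqpd_path, fasta_path, on_missing = "skip") {
  s <- read_set(set_path)
  h <- open_sqpd(sqpd_path)
  on.exit(close_sqpd(h))
  entries <- resolve_set(s, h, on_missing = on_missing)
  write_fasta(entries, fasta_path)
  invisible(length(entries))
}

#' Snapshot every accession of an SQPD as a SET
#' @param sqpd_path Input SQPD; `set_path` output SET file.
#' @param set_name Name recorded in the SET.
#' @return The [entry_set()], invisibly.
#' @export
sqpd_to_set <- function(sqpd_path, set_path, set_name = "all-entries") {
  h <- open_sqpd(sqpd_path)
  on.exit(close_sqpd(h))
  m <- sqpd_meta(h)
  s <- entry_set(query_entries(h), set_name = set_name,
                 db_name = m$db_name, db_version = m$db_version)
  write_set(s, set_path)
  invisible(s)
}
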