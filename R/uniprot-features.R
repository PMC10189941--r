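# UniProt tab-separated annotation tables -> proteoform features.
#
# A feature cell concatenates intervals of one feature class, e.g.
#   SIGNAL 1..22; /evidence="ECO:0000255"
#   VARIANT 54; /note="A -> T"; VARIANT 100..101; /note="missing"
# Single positions appear without "..". Uncertain bounds ("<", ">", "?") and
# unknown feature classes are skipped with a warning rather than failing the
# whole row.

#' Map one UniProt annotation-table row to features
#'
#' Scans every feature column of a row (named cells) and parses the UniProt
#' cell grammar into [feature()] objects, using the controlled-vocabulary
#' mapping: Signal peptide -> `SIGNAL`, Chain -> `CHAIN`, Propeptide ->
#' `PROPEP`, Transit peptide -> `TRANSIT`, Initiator methionine ->
#' `INIT_MET`, Natural variant -> `VARIANT` (payload = replacement residues
#' from `/note="X -> Y"`), Modified residue -> `MOD_RES` (payload = note
#' text), Sequence conflict -> `CONFLICT`. Multi-interval cells are split
#' into separate features.
#'
#' @param row Named list/character vector: column label -> cell text.
#' @return List of [feature()] objects (possibly empty).
#' @export
map_uniprot_features <- function(row) {
  feats <- list()
  for (col in names(row)) {
    kind <- unname(UNIPROT_FEATURE_MAP[col])
    if (is.na(kind)) next
    cell <- row[[col]]
    if (is.null(cell) || is.na(cell) || !nzchar(trimws(cell))) next
    feats <- c(feats, parse_feature_cell(cell, default_kind = kind))
  }
  feats
}

#' Parse one UniProt feature cell
#'
#' @param cell Cell text in the UniProt TSV feature grammar.
#' @param default_kind Feature kind to assume when the cell's TYPE token is
#'   not itself a known kind (the column label decides the class).
#' @return List of [feature()] objects.
#' @export
parse_feature_cell <- function(cell, default_kind = NULL) {
  cell <- trimws(cell)
  if (!nzchar(cell)) return(list())
  # every interval opens with "TYPE <range>" at cell start or after "; "
  pat <- "(?:^|;\\s*)([A-Z][A-Z_]+)\\s+([<>?]?\\d*(?:\\.\\.[<>?]?\\d*)?|\\?)"
  m <- gregexpr(pat, cell, perl = TRUE)[[1]]
  if (m[1] == -1L)
    sdk_stop("malformed_feature_cell", paste("unparseable feature cell:", cell))
  starts <- as.integer(m)
  ends <- c(starts[-1] - 1L, nchar(cell))
  feats <- list()
  for (i in seq_along(starts)) {
    seg <- substr(cell, starts[i], ends[i])
    mm <- regmatches(seg, regexec(pat, seg, perl = TRUE))[[1]]
    type_token <- mm[2]
    range_txt <- mm[3]
    kind <- if (type_token %in% names(UNIPROT_CELL_TYPES)) UNIPROT_CELL_TYPES[[type_token]]
            else default_kind
    if (is.null(kind)) {
      sdk_warn("unknown_feature_type", paste("skipping unknown feature type:", type_token))
      next
    }
    if (grepl("[<>?]", range_txt) || !nzchar(range_txt)) {
      sdk_warn("uncertain_position",
               sprintf("skipping %s with uncertain position '%s'", kind, range_txt))
      next
    }
    bounds <- strsplit(range_txt, "..", fixed = TRUE)[[1]]
    start <- as.integer(bounds[1])
    end <- if (length(bounds) > 1L) as.integer(bounds[2]) else start
    if (is.na(start) || is.na(end))
      sdk_stop("malformed_feature_cell", paste("bad range in feature cell:", seg))
    note <- regmatches(seg, regexec('/note="([^"]*)"', seg))[[1]]
    payload <- ""
    if (kind == "VARIANT") {
      if (length(note)) {
        repl <- regmatches(note[2], regexec("->\\s*(\\S+)", note[2]))[[1]]
        payload <- if (length(repl)) repl[2] else note[2]
      }
    } else if (length(note)) {
      payload <- note[2]
    }
    feats[[length(feats) + 1L]] <-
      feature(kind, start, end, payload = payload, source_key = type_token)
  }
  feats
}

#' Read a UniProt-style annotation table
#'
#' @param path TSV file with a header row; an `Entry` (or `id_column`)
#'   column identifies the protein.
#' @param id_column Name of the accession column.
#' @return A data.frame (character columns, one row per protein).
#' @export
read_annotation_table <- function(path, id_column = "Entry") {
  if (!file.exists(path)) sdk_stop("file_unreadable", paste("no such file:", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (!id_column %in% names(df))
    sdk_stop("missing_column", sprintf("annotation table lacks column '%s'", id_column))
  df
}

#' Attach table-derived features to entries
#'
#' For every entry whose accession appears in the annotation table, replaces
#' its features with the table-derived ones ([map_uniprot_features()]).
#' Entries without a table row are left featureless.
#'
#' @param entries List of [protein_entry()] objects.
#' @param table Data frame from [read_annotation_table()].
#' @param id_column Accession column name.
#' @return The updated entry list.
#' @export
apply_feature_table <- function(entries, table, id_column = "Entry") {
  if (!id_column %in% names(table))
    sdk_stop("missing_column", sprintf("annotation table lacks column '%s'", id_column))
  idx <- match(vapply(entries, `[[`, character(1), "accession"), table[[id_column]])
  lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    if (is.na(idx[i])) return(e)
    row <- as.list(table[idx[i], , drop = FALSE])
    feats <- withCallingHandlers(map_uniprot_features(row),
      warning = function(w) invokeRestart("muffleWarning"))
    len <- nchar(e$sequence)
    keep <- Filter(function(f) f$end <= len, feats)
    if (length(keep) < length(feats))
      sdk_warn("feature_out_of_range",
               sprintf("%s: dropped %d feature(s) beyond sequence end",
                       e$accession, length(feats) - length(keep)))
    protein_entry(e$accession, e$sequence, description = e$description,
                  prefix = e$prefix, features = keep, meta = e$meta)
  })
}
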