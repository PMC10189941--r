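#' Extract mature proteoform sequences
#'
#' Derives the post-processing forms of a precursor from its features:
#' signal/transit/propeptides and processed chains are sliced at their
#' annotated ranges, and an `INIT_MET` annotation emits the sequence with
#' the initiator methionine removed (range `2..L`, kind
#' `INIT_MET_REMOVED`). Each form's name encodes the source accession, the
#' polypeptide kind and the truncated range as
#' `<accession>|<KIND>|<start>-<end>`.
#'
#' @param entry A [protein_entry()] with features.
#' @param kinds Feature kinds to honour (default all processing kinds).
#' @param min_len Drop forms shorter than this many residues (default 1:
#'   keep everything; raise to e.g. 7 for search-ready databases).
#' @return List of `mature_form` records with fields `source_accession`,
#'   `form_kind`, `start`, `end`, `sequence`, `name`.
#' @export
extract_mature_forms <- function(entry,
                                 kinds = c("SIGNAL", "CHAIN", "PROPEP",
                                           "TRANSIT", "INIT_MET"),
                                 min_len = 1L) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  len <- nchar(entry$sequence)
  forms <- list()
  push <- function(kind, start, end) {
    if (start > end) return()
    if (end > len)
      sdk_stop("feature_out_of_range",
               sprintf("%s feature %d..%d exceeds sequence length %d",
                       kind, start, end, len))
    seq <- substr(entry$sequence, start, end)
    if (nchar(seq) < min_len) return()
    forms[[length(forms) + 1L]] <<- structure(
      list(source_accession = entry$accession, form_kind = kind,
           start = start, end = end, sequence = seq,
           name = sprintf("%s|%s|%d-%d", entry$accession, kind, start, end)),
      class = "mature_form")
  }
  for (f in entry$features) {
    if (!f$kind %in% kinds) next
    if (f$kind == "INIT_MET") {
      push("INIT_MET_REMOVED", f$end + 1L, len)
    } else {
      push(f$kind, f$start, f$end)
    }
  }
  forms
}

#' Convert mature forms to FASTA-ready entries
#'
#' @param forms List of `mature_form` records.
#' @return List of [protein_entry()] objects named by the composed form
#'   names.
#' @export
mature_forms_to_entries <- function(forms) {
  lapply(forms, function(f)
    protein_entry(f$name, f$sequence,
                  description = sprintf("%s form of %s", f$form_kind, f$source_accession),
                  prefix = "mature"))
}
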