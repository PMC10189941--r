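#' Generate reversed decoy entries
#'
#' Builds the reversed-sequence decoy database used for false discovery rate
#' estimation in target-decoy searching: each decoy sequence is the full
#' character reversal of its target, the decoy accession is `tag` prepended
#' to the original accession, and no features are carried over.
#'
#' @param entries List of [protein_entry()] targets.
#' @param tag Decoy accession prefix (non-empty), default `"rev_"`.
#' @param mode `"decoy_only"` returns only decoys; `"concat"` returns the
#'   targets followed by their decoys.
#' @return List of [protein_entry()] objects.
#' @export
#' @examples
#' e <- protein_entry("P1", "ABCDEF")
#' make_decoys(list(e))[[1]]$sequence  # "FEDCBA"
make_decoys <- function(entries, tag = "rev_", mode = c("decoy_only", "concat")) {
  mode <- match.arg(mode)
  if (!is_string(tag) || !nzchar(tag)) sdk_stop("invalid_argument", "tag must be non-empty")
  accs <- vapply(entries, `[[`, character(1), "accession")
  clash <- startsWith(accs, tag)
  if (any(clash))
    sdk_stop("tag_collision",
             paste("target accession already carries the decoy tag:", accs[clash][1]))
  decoys <- lapply(entries, function(e) {
    protein_entry(paste0(tag, e$accession), reverse_sequence(e$sequence),
                  description = e$description, prefix = e$prefix)
  })
  if (mode == "concat") c(entries, decoys) else decoys
}

reverse_sequence <- function(seq) {
  paste(rev(strsplit(seq, "")[[1]]), collapse = "")
}
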