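# Synthetic fixtures: toy proteomes with randomized proteoform features,
# annotation tables in the UniProt TSV cell grammar, and random transcripts.
# These emulate the *shape* of real inputs (header dialects, feature
# geometry, table grammar), not their biology: residue usage is uniform and
# feature placement is random, so they exercise parsers and round-trips but
# say nothing about real-proteome statistics.

#' Random amino-acid sequence
#' @param len Length in residues.
#' @return Sequence string over the 20 standard residues.
#' @export
random_protein_sequence <- function(len) {
  paste(sample(AA_STANDARD, len, replace = TRUE), collapse = "")
}

#' Random nucleotide sequence
#' @param len Length in nt.
#' @return DNA sequence string.
#' @export
random_na_sequence <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate a toy proteome
#'
#' `n` entries with UniProt-style accessions and, optionally, randomized
#' proteoform features: a signal peptide over residues `1..k` followed by
#' the mature chain `k+1..L` (about half the entries), single-residue
#' variants and modified residues at random positions. Uses the session
#' RNG; set a seed beforehand for reproducibility.
#'
#' @param n Number of entries.
#' @param len_range Sequence length range (residues).
#' @param with_features Attach randomized features.
#' @param prefix Accession prefix (entries are `<prefix>00001`, ...).
#' @return List of [protein_entry()] objects.
#' @export
random_proteome <- function(n = 100L, len_range = c(50L, 400L),
                            with_features = TRUE, prefix = "P") {
  lapply(seq_len(n), function(i) {
    len <- sample(len_range[1]:len_range[2], 1L)
    seq <- random_protein_sequence(len)
    feats <- list()
    if (with_features) {
      if (stats::runif(1) < 0.5 && len > 30L) {
        k <- sample(15:25, 1L)
        feats <- c(feats, list(feature("SIGNAL", 1L, k),
                               feature("CHAIN", k + 1L, len)))
      }
      n_var <- stats::rpois(1, 0.8)
      for (j in seq_len(n_var)) {
        pos <- sample(len, 1L)
        feats <- c(feats, list(feature("VARIANT", pos, pos,
                                       payload = sample(AA_STANDARD, 1L))))
      }
      n_mod <- stats::rpois(1, 0.6)
      for (j in seq_len(n_mod)) {
        pos <- sample(len, 1L)
        feats <- c(feats, list(feature("MOD_RES", pos, pos,
                                       payload = sample(c("Phosphoserine",
                                                          "Phosphothreonine",
                                                          "N6-acetyllysine"), 1L))))
      }
    }
    protein_entry(sprintf("%s%05d", prefix, i), seq,
                  description = sprintf("synthetic protein %d", i),
                  prefix = "sp",
                  features = feats,
                  meta = list(GN = sprintf("gene%d", i), OX = "10090"))
  })
}

#' Render entry features as a UniProt-style annotation table
#'
#' Inverse of [map_uniprot_features()] on the modeled fields: writes each
#' entry's features back into the UniProt TSV cell grammar so that
#' table-driven ingestion can be tested end to end.
#'
#' @param entries List of [protein_entry()] objects.
#' @return A data.frame with `Entry`, naming columns and one column per
#'   feature class.
#' @export
synthetic_annotation_table <- function(entries) {
  kind_to_col <- stats::setNames(names(UNIPROT_FEATURE_MAP), UNIPROT_FEATURE_MAP)
  cols <- c("Entry", "Gene Names", "Protein names", "Organism", "Organism (ID)",
            names(UNIPROT_FEATURE_MAP))
  rows <- lapply(entries, function(e) {
    row <- stats::setNames(as.list(rep("", length(cols))), cols)
    row[["Entry"]] <- e$accession
    row[["Gene Names"]] <- e$meta[["GN"]] %||% ""
    row[["Protein names"]] <- e$description
    row[["Organism"]] <- "Mus musculus"
    row[["Organism (ID)"]] <- e$meta[["OX"]] %||% ""
    for (f in e$features) {
      col <- kind_to_col[[f$kind]]
      cell <- if (f$start == f$end) sprintf("%s %d", f$kind, f$start)
              else sprintf("%s %d..%d", f$kind, f$start, f$end)
      if (f$kind == "VARIANT" && nzchar(f$payload))
        cell <- sprintf('%s; /note="%s -> %s"', cell,
                        substr(e$sequence, f$start, f$start), f$payload)
      else if (nzchar(f$payload))
        cell <- sprintf('%s; /note="%s"', cell, f$payload)
      row[[col]] <- if (nzchar(row[[col]])) paste0(row[[col]], "; ", cell) else cell
    }
    as.data.frame(row, check.names = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate random transcripts
#'
#' @param n Number of transcripts.
#' @param len_range Length range in nt.
#' @param prefix Transcript id prefix.
#' @return List of records with `accession` and `sequence`.
#' @export
random_transcripts <- function(n = 50L, len_range = c(30L, 600L), prefix = "tx") {
  lapply(seq_len(n), function(i) {
    list(accession = sprintf("%s%03d", prefix, i),
         description = "synthetic transcript",
         sequence = random_na_sequence(sample(len_range[1]:len_range[2], 1L)))
  })
}
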