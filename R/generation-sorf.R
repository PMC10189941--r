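# Small-ORF / SEP prediction on linear and circular transcripts.
#
# Linear transcripts are scanned per frame (1..3 forward, 4..6 on the
# reverse complement); circular transcripts are scanned at every forward
# position with the read head advancing modulo the circle length, so an ORF
# may cross the back-splice junction — each L -> 1 passage from the start
# codon through the stop codon is counted as one junction crossing. On a
# circle whose length is not a multiple of 3 the reading frame only repeats
# after three full traversals, so translation is bounded at three wraps.

#' Translate a nucleotide sequence
#'
#' Standard genetic code (NCBI table 1) by default; codons containing `N`
#' translate to `X`; stop codons to `*`.
#'
#' @param na_seq DNA sequence (RNA is normalized first), length divisible
#'   by 3.
#' @param code_table NCBI genetic-code table id (passed to
#'   [Biostrings::getGeneticCode()]).
#' @return Amino-acid string.
#' @export
#' @examples
#' translate_na("ATGAAATAG")  # "MK*"
translate_na <- function(na_seq, code_table = "1") {
  na_seq <- validate_sequence(na_seq, "NA")
  if (nchar(na_seq) %% 3L != 0L)
    sdk_stop("length_not_multiple_of_three",
             sprintf("sequence length %d is not a multiple of 3", nchar(na_seq)))
  codons <- substring(na_seq, seq(1L, nchar(na_seq) - 2L, 3L),
                      seq(3L, nchar(na_seq), 3L))
  paste(translate_codons(codons, code_table), collapse = "")
}

translate_codons <- function(codons, code_table = "1") {
  code <- Biostrings::getGeneticCode(as.character(code_table))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  aa
}

stop_codons_for <- function(code_table = "1") {
  code <- Biostrings::getGeneticCode(as.character(code_table))
  names(code)[code == "*"]
}

revcomp <- function(na_seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(na_seq, "")[[1]]])), collapse = "")
}

.sorf_record <- function(transcript_id, frame, start_codon, topology,
                         orf_start, orf_end_linearized, peptide,
                         junction_crossings, terminated) {
  structure(
    list(transcript_id = transcript_id, frame = as.integer(frame),
         start_codon = start_codon, topology = topology,
         orf_start = as.integer(orf_start),
         orf_end_linearized = as.integer(orf_end_linearized),
         peptide = peptide, junction_crossings = as.integer(junction_crossings),
         terminated = terminated),
    class = "sorf_record")
}

#' Find small ORFs on a linear transcript
#'
#' For each frame and each in-frame occurrence of a start codon, translation
#' extends codon-by-codon to the first stop codon. ORF coordinates are
#' 1-based nucleotide positions on the scanned strand (frames 4-6 are
#' positions on the reverse complement).
#'
#' @param transcript_id Identifier carried into the records.
#' @param na_seq Nucleotide sequence (length >= 3).
#' @param start_codons Character vector of 3-mers, or a preset name
#'   (`"canonical"` = ATG, `"near-cognate"` = ATG, CTG, GTG, TTG, ACG).
#' @param min_pep,max_pep Peptide length bounds (stop excluded); `max_pep =
#'   NULL` means unbounded.
#' @param strands `"forward"` or `"both"`.
#' @param require_stop If `FALSE`, run-off ORFs reaching the sequence end
#'   without a stop are also reported with `terminated = FALSE`.
#' @param longest_only Collapse nested starts sharing a stop to the 5'-most.
#' @param code_table NCBI genetic-code table id.
#' @return List of `sorf_record` objects.
#' @export
find_sorfs_linear <- function(transcript_id, na_seq, start_codons = "ATG",
                              min_pep = 7L, max_pep = 100L,
                              strands = c("forward", "both"),
                              require_stop = TRUE, longest_only = FALSE,
                              code_table = "1") {
  strands <- match.arg(strands)
  na_seq <- validate_sequence(na_seq, "NA")
  if (nchar(na_seq) < 3L) sdk_stop("invalid_argument", "transcript shorter than one codon")
  start_codons <- resolve_start_codons(start_codons)
  stops <- stop_codons_for(code_table)
  records <- list()
  strand_seqs <- list(forward = na_seq)
  if (strands == "both") strand_seqs$reverse <- revcomp(na_seq)
  for (strand in names(strand_seqs)) {
    S <- strand_seqs[[strand]]
    L <- nchar(S)
    for (offset in 0:2) {
      if (L - offset < 3L) next
      frame <- offset + 1L + if (strand == "reverse") 3L else 0L
      first <- seq.int(offset + 1L, L - 2L, by = 3L)
      codons <- substring(S, first, first + 2L)
      aa <- translate_codons(codons, code_table)
      is_start <- codons %in% start_codons
      is_stop <- codons %in% stops
      stop_idx <- which(is_stop)
      for (si in which(is_start)) {
        nxt <- stop_idx[stop_idx >= si]
        if (length(nxt)) {
          stop_at <- nxt[1]
          pep <- paste(aa[seq.int(si, stop_at - 1L)], collapse = "")
          rec <- .sorf_record(transcript_id, frame, codons[si], "linear",
                              first[si], first[stop_at] + 2L, pep, 0L, TRUE)
        } else {
          if (require_stop) next
          pep <- paste(aa[seq.int(si, length(aa))], collapse = "")
          rec <- .sorf_record(transcript_id, frame, codons[si], "linear",
                              first[si], first[length(first)] + 2L, pep, 0L, FALSE)
        }
        if (nchar(rec$peptide) < min_pep) next
        if (!is.null(max_pep) && nchar(rec$peptide) > max_pep) next
        records[[length(records) + 1L]] <- rec
      }
    }
  }
  if (longest_only) records <- collapse_nested_starts(records)
  records
}

resolve_start_codons <- function(start_codons) {
  if (length(start_codons) == 1L && start_codons %in% names(START_CODON_PRESETS))
    return(START_CODON_PRESETS[[start_codons]])
  codons <- toupper(gsub("U", "T", start_codons))
  if (any(!grepl("^[ACGT]{3}$", codons)))
    sdk_stop("invalid_argument", "start codons must be 3-mers over ACGT/U")
  codons
}

# keep only the 5'-most start per (frame, stop end) group
collapse_nested_starts <- function(records) {
  if (!length(records)) return(records)
  key <- vapply(records, function(r)
    paste(r$transcript_id, r$frame, r$orf_end_linearized, r$terminated), character(1))
  starts <- vapply(records, `[[`, integer(1), "orf_start")
  keep <- unlist(lapply(split(seq_along(records), key), function(ix)
    ix[which.min(starts[ix])]), use.names = FALSE)
  records[sort(keep)]
}

#' Find small ORFs on a circular transcript
#'
#' Candidate starts are tested at every forward position `1..L` (all three
#' phases); translation proceeds with the nucleotide index taken modulo the
#' circle length and stops at the first stop codon or when the read head
#' returns to the start position in the same phase (at most `max_wraps`
#' traversals: three when the length is not a multiple of 3, one when it
#' is). `junction_crossings` counts the passages over the `L -> 1`
#' back-splice junction from the start codon through the stop codon
#' inclusive. Non-terminating ORFs are reported with `terminated = FALSE`
#' and the peptide truncated at cycle closure.
#'
#' @inheritParams find_sorfs_linear
#' @param max_wraps Maximum full traversals of the circle (default 3, after
#'   which the reading frame necessarily repeats).
#' @return List of `sorf_record` objects with `topology = "circular"`.
#' @export
find_sorfs_circular <- function(transcript_id, na_seq, start_codons = "ATG",
                                min_pep = 7L, max_pep = 100L, max_wraps = 3L,
                                code_table = "1") {
  na_seq <- validate_sequence(na_seq, "NA")
  L <- nchar(na_seq)
  if (L < 3L) sdk_stop("invalid_argument", "transcript shorter than one codon")
  start_codons <- resolve_start_codons(start_codons)
  stops <- stop_codons_for(code_table)
  chars <- strsplit(na_seq, "")[[1]]
  circ_codon <- function(p) {
    idx <- ((p - 1L + 0:2) %% L) + 1L
    paste(chars[idx], collapse = "")
  }
  # codon budget before the frame repeats
  max_codons <- if (L %% 3L == 0L) L %/% 3L else (L * min(max_wraps, 3L)) %/% 3L
  records <- list()
  for (p in 1:L) {
    first <- circ_codon(p)
    if (!first %in% start_codons) next
    codons <- character(max_codons)
    terminated <- FALSE
    k <- 0L
    q <- p
    while (k < max_codons) {
      cd <- circ_codon(q)
      k <- k + 1L
      codons[k] <- cd
      if (cd %in% stops) { terminated <- TRUE; break }
      q <- q + 3L
    }
    codons <- codons[seq_len(k)]
    aa <- translate_codons(codons)
    pep <- if (terminated) paste(aa[-k], collapse = "") else paste(aa, collapse = "")
    if (nchar(pep) < min_pep) next
    if (!is.null(max_pep) && nchar(pep) > max_pep) next
    end_lin <- p + 3L * k - 1L
    # crossings: transitions q -> q+1 with q a multiple of L, q in [p, end_lin-1]
    crossings <- max(0L, (end_lin - 1L) %/% L - (p - 1L) %/% L)
    records[[length(records) + 1L]] <-
      .sorf_record(transcript_id, ((p - 1L) %% 3L) + 1L, first, "circular",
                   p, end_lin, pep, crossings, terminated)
  }
  records
}

#' Compose the name of an ORF record
#'
#' `<transcript_id>|F<frame>|<start_codon>|<lin|cir>|<start>-<end>`, with a
#' trailing `|J<crossings>` for circular ORFs.
#'
#' @param r A `sorf_record`.
#' @return Name string.
#' @export
sorf_name <- function(r) {
  base <- sprintf("%s|F%d|%s|%s|%d-%d", r$transcript_id, r$frame, r$start_codon,
                  if (r$topology == "circular") "cir" else "lin",
                  r$orf_start, r$orf_end_linearized)
  if (r$topology == "circular") base <- sprintf("%s|J%d", base, r$junction_crossings)
  base
}

#' Unique names for a batch of ORF records
#'
#' Applies [sorf_name()] and resolves collisions within the run by
#' suffixing `_2`, `_3`, ...
#'
#' @param records List of `sorf_record` objects.
#' @return Character vector of unique names.
#' @export
sorf_names <- function(records) {
  nm <- vapply(records, sorf_name, character(1))
  counts <- list()
  for (i in seq_along(nm)) {
    k <- counts[[nm[i]]] %||% 0L
    counts[[nm[i]]] <- k + 1L
    if (k > 0L) nm[i] <- paste0(nm[i], "_", k + 1L)
  }
  nm
}

#' Convert ORF records to FASTA-ready protein entries
#'
#' @param records List of `sorf_record` objects.
#' @return List of [protein_entry()] objects named with [sorf_names()].
#' @export
sorfs_to_entries <- function(records) {
  nm <- sorf_names(records)
  lapply(seq_along(records), function(i) {
    r <- records[[i]]
    protein_entry(nm[i], r$peptide,
                  description = sprintf("%s sORF-encoded peptide from %s",
                                        r$topology, r$transcript_id),
                  prefix = "sep")
  })
}

#' Tabulate ORF records
#'
#' @param records List of `sorf_record` objects.
#' @return A data.frame with one row per record (plus a `name` column).
#' @export
sorfs_to_table <- function(records) {
  if (!length(records)) {
    return(data.frame(name = character(), transcript_id = character(),
                      frame = integer(), start_codon = character(),
                      topology = character(), orf_start = integer(),
                      orf_end_linearized = integer(), peptide = character(),
                      junction_crossings = integer(), terminated = logical(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    name = sorf_names(records),
    transcript_id = vapply(records, `[[`, character(1), "transcript_id"),
    frame = vapply(records, `[[`, integer(1), "frame"),
    start_codon = vapply(records, `[[`, character(1), "start_codon"),
    topology = vapply(records, `[[`, character(1), "topology"),
    orf_start = vapply(records, `[[`, integer(1), "orf_start"),
    orf_end_linearized = vapply(records, `[[`, integer(1), "orf_end_linearized"),
    peptide = vapply(records, `[[`, character(1), "peptide"),
    junction_crossings = vapply(records, `[[`, integer(1), "junction_crossings"),
    terminated = vapply(records, `[[`, logical(1), "terminated"),
    stringsAsFactors = FALSE
  )
}
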