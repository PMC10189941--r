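# Independent oracles used by the property-style tests. These re-derive
# expected results by direct enumeration, without going through the code
# paths they check.

as_tempfile <- function(text, ext = "") {
  p <- tempfile(fileext = ext)
  writeLines(strsplit(text, "\n")[[1]], p)
  p
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(map[strsplit(s, "")[[1]]])), collapse = "")
}

oracle_translate <- function(codons) {
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  aa
}

# Brute-force linear ORF scan: test every nucleotide position for a start
# codon, then walk forward codon by codon to the first stop.
oracle_orfs_linear <- function(id, seq, starts, min_pep = 1L, max_pep = NULL,
                               strands = "forward", require_stop = TRUE) {
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  strand_seqs <- list(forward = seq)
  if (strands == "both") strand_seqs$reverse <- oracle_revcomp(seq)
  for (strand in names(strand_seqs)) {
    S <- strand_seqs[[strand]]
    L <- nchar(S)
    for (p in seq_len(max(L - 2L, 0L))) {
      cod <- substr(S, p, p + 2L)
      if (!cod %in% starts) next
      q <- p
      codons <- character()
      terminated <- FALSE
      while (q + 2L <= L) {
        c2 <- substr(S, q, q + 2L)
        codons <- c(codons, c2)
        if (c2 %in% stops) { terminated <- TRUE; break }
        q <- q + 3L
      }
      if (!terminated && require_stop) next
      aa <- oracle_translate(codons)
      pep <- if (terminated) paste(aa[-length(aa)], collapse = "")
             else paste(aa, collapse = "")
      if (nchar(pep) < min_pep) next
      if (!is.null(max_pep) && nchar(pep) > max_pep) next
      frame <- ((p - 1L) %% 3L) + 1L + if (strand == "reverse") 3L else 0L
      end <- if (terminated) q + 2L else p + 3L * length(codons) - 1L
      out[[length(out) + 1L]] <- sprintf("%s|F%d|%s|%d-%d|%s|%s",
                                         id, frame, cod, p, end, pep, terminated)
    }
  }
  sort(as.character(unlist(out)))
}

sorf_fingerprints <- function(records) {
  sort(vapply(records, function(r)
    sprintf("%s|F%d|%s|%d-%d|%s|%s", r$transcript_id, r$frame, r$start_codon,
            r$orf_start, r$orf_end_linearized, r$peptide, r$terminated),
    character(1)))
}

# Naive quadratic motif count for plain (wildcard-free) patterns.
oracle_motif_count <- function(seq, pattern) {
  n <- nchar(seq); m <- nchar(pattern)
  if (m > n) return(0L)
  sum(vapply(seq_len(n - m + 1L), function(i)
    substr(seq, i, i + m - 1L) == pattern, logical(1)))
}

# In-memory evaluation of a filter_spec over a list of protein entries.
oracle_filter <- function(entries, spec) {
  ok <- vapply(entries, function(e) {
    len <- nchar(e$sequence)
    mass <- average_mass(e$sequence)
    kinds <- vapply(e$features, `[[`, character(1), "kind")
    for (cl in spec$clauses) {
      val <- switch(cl$field, length = len, mass = mass, NULL)
      pass <- switch(cl$op,
        ge = val >= as.numeric(cl$value[1]),
        le = val <= as.numeric(cl$value[1]),
        between = val >= as.numeric(cl$value[1]) && val <= as.numeric(cl$value[2]),
        has = cl$value %in% kinds,
        matches = count_motifs(e, cl$value)[[1]] > 0L,
        `in` = e$accession %in% cl$value)
      if (!pass) return(FALSE)
    }
    TRUE
  }, logical(1))
  sort(vapply(entries[ok], `[[`, character(1), "accession"))
}

# Random filter specs over the fixture database's observable fields.
random_filter_spec <- function(entries) {
  lens <- vapply(entries, function(e) nchar(e$sequence), numeric(1))
  n_clauses <- sample(1:3, 1)
  clauses <- lapply(seq_len(n_clauses), function(i) {
    kind <- sample(c("length", "mass", "feature", "motif"), 1)
    switch(kind,
      length = {
        lo <- sample(round(range(lens)[1]):round(range(lens)[2]), 1)
        if (stats::runif(1) < 0.5) clause("length", "ge", lo)
        else clause("length", "between", c(lo, lo + sample(10:150, 1)))
      },
      mass = clause("mass", sample(c("ge", "le"), 1),
                    stats::runif(1, 6000, 40000)),
      feature = clause("feature_key", "has",
                       sample(c("SIGNAL", "CHAIN", "VARIANT", "MOD_RES"), 1)),
      motif = clause("motif", "matches",
                     paste(sample(c("A", "C", "D", "G", "K", "x"), sample(2:3, 1),
                                  replace = TRUE), collapse = ""))
    )
  })
  filter_spec(clauses)
}

# Shared fixture: a small featured proteome and its SQPD database.
make_fixture_db <- function(n = 40, seed = 42, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("fixdb")
    dir.create(dir)
  }
  set.seed(seed)
  entries <- random_proteome(n, len_range = c(30L, 300L))
  path <- file.path(dir, "fixture.sqpd")
  h <- create_sqpd(path, database_meta("toy", "1", db_source = "custom"),
                   overwrite = TRUE)
  add_entries(h, entries)
  list(entries = entries, handle = h, path = path)
}
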