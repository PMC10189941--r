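test_that("decoy generation reverses sequences and is an involution", {
  e <- protein_entry("P1", "ABCDEF")
  d <- make_decoys(list(e))[[1]]
  expect_equal(d$sequence, "FEDCBA")
  expect_equal(d$accession, "rev_P1")
  expect_length(d$features, 0)

  set.seed(14)
  entries <- random_proteome(20, with_features = FALSE)
  once <- make_decoys(entries, tag = "d_")
  twice <- make_decoys(once, tag = "x_")
  for (i in seq_along(entries)) {
    expect_identical(twice[[i]]$sequence, entries[[i]]$sequence)
    expect_identical(sort(strsplit(once[[i]]$sequence, "")[[1]]),
                     sort(strsplit(entries[[i]]$sequence, "")[[1]]))
  }

  both <- make_decoys(entries, mode = "concat")
  expect_length(both, 40)
  expect_identical(both[[1]]$sequence, entries[[1]]$sequence)

  expect_error(make_decoys(c(entries, list(protein_entry("rev_Q", "ACD")))),
               class = "seqdbkit_tag_collision")
})

test_that("translation follows the standard code with N -> X and stops as *", {
  expect_equal(translate_na("ATGAAATAG"), "MK*")
  expect_equal(translate_na("ATGNNN"), "MX")
  expect_equal(translate_na("augaaa"), "MK")
  expect_error(translate_na("ATGA"), class = "seqdbkit_length_not_multiple_of_three")
})

test_that("mature forms slice precursors at their annotated ranges", {
  e <- protein_entry("P1", "MKKKAAAACCCC",
                     features = list(feature("SIGNAL", 1, 4),
                                     feature("CHAIN", 5, 12)))
  forms <- extract_mature_forms(e)
  expect_length(forms, 2)
  expect_equal(forms[[1]]$sequence, "MKKK")
  expect_equal(forms[[1]]$name, "P1|SIGNAL|1-4")
  expect_equal(forms[[2]]$sequence, "AAAACCCC")
  expect_equal(forms[[2]]$name, "P1|CHAIN|5-12")

  im <- protein_entry("P2", "MABC", features = list(feature("INIT_MET", 1, 1)))
  f <- extract_mature_forms(im)
  expect_length(f, 1)
  expect_equal(f[[1]]$form_kind, "INIT_MET_REMOVED")
  expect_equal(f[[1]]$sequence, "ABC")
  expect_equal(c(f[[1]]$start, f[[1]]$end), c(2L, 4L))

  expect_length(extract_mature_forms(protein_entry("P3", "ACDEF")), 0)

  # every form is the exact substring of its source at the recorded range
  set.seed(15)
  for (e in random_proteome(15)) {
    for (f in extract_mature_forms(e)) {
      expect_identical(f$sequence, substr(e$sequence, f$start, f$end))
    }
  }

  # min_len drops short forms
  expect_length(extract_mature_forms(e, min_len = 100), 0)
})

test_that("linear ORF finding matches hand-worked frames", {
  r <- find_sorfs_linear("tx1", "ATGAAATAG", min_pep = 1)
  expect_length(r, 1)
  expect_equal(r[[1]]$frame, 1L)
  expect_equal(r[[1]]$peptide, "MK")
  expect_equal(c(r[[1]]$orf_start, r[[1]]$orf_end_linearized), c(1L, 9L))
  expect_true(r[[1]]$terminated)
  expect_equal(r[[1]]$junction_crossings, 0L)
  expect_equal(sorf_name(r[[1]]), "tx1|F1|ATG|lin|1-9")

  r2 <- find_sorfs_linear("tx1", "CATGAAATAGC", min_pep = 1)
  expect_length(r2, 1)
  expect_equal(r2[[1]]$frame, 2L)
  expect_equal(r2[[1]]$peptide, "MK")
  expect_equal(c(r2[[1]]$orf_start, r2[[1]]$orf_end_linearized), c(2L, 10L))
})

test_that("linear ORF finding equals the brute-force scan on random transcripts", {
  set.seed(16)
  txs <- random_transcripts(25, len_range = c(30L, 400L))
  for (starts in list("ATG", c("ATG", "CTG", "GTG", "TTG", "ACG"))) {
    for (tx in txs) {
      got <- find_sorfs_linear(tx$accession, tx$sequence, start_codons = starts,
                               min_pep = 1, max_pep = NULL, strands = "both",
                               require_stop = FALSE)
      expect_identical(sorf_fingerprints(got),
                       oracle_orfs_linear(tx$accession, tx$sequence, starts,
                                          strands = "both", require_stop = FALSE))
    }
  }
})

test_that("ORF length bookkeeping holds for terminated records", {
  set.seed(17)
  for (tx in random_transcripts(10)) {
    for (r in find_sorfs_linear(tx$accession, tx$sequence, min_pep = 1)) {
      if (r$terminated)
        expect_equal(nchar(r$peptide) * 3L + 3L,
                     r$orf_end_linearized - r$orf_start + 1L)
      expect_equal(r$junction_crossings, 0L)
    }
  }
})

test_that("circular translation wraps the junction and counts crossings", {
  r <- find_sorfs_circular("tx2", "ATGAAAAAAA", min_pep = 1)
  expect_length(r, 1)
  expect_equal(r[[1]]$peptide, "MKKNEKK")
  expect_equal(r[[1]]$junction_crossings, 2L)
  expect_true(r[[1]]$terminated)
  expect_equal(sorf_name(r[[1]]), "tx2|F1|ATG|cir|1-24|J2")

  # independent check: three linearized copies read from position 1
  lin <- strrep("ATGAAAAAAA", 3)
  expect_equal(translate_na(substr(lin, 1, 21)), "MKKNEKK")
  expect_equal(substr(lin, 22, 24), "TGA")

  r2 <- find_sorfs_circular("tx3", "ATGTAA", min_pep = 1)
  expect_length(r2, 1)
  expect_equal(r2[[1]]$peptide, "M")
  expect_equal(r2[[1]]$junction_crossings, 0L)

  # no stop in any phase, length not divisible by 3: one residue per nt
  noStop <- "ATGCAAAAAAA"  # L = 11; the only T reads as TGC off-frame
  r3 <- find_sorfs_circular("tx4", noStop, min_pep = 1, max_pep = NULL)
  starts_at_1 <- Filter(function(r) r$orf_start == 1L, r3)
  expect_false(starts_at_1[[1]]$terminated)
  expect_equal(nchar(starts_at_1[[1]]$peptide), nchar(noStop))
})

test_that("circular scan is rotation-invariant in its peptide multiset", {
  set.seed(18)
  for (i in 1:8) {
    L <- sample(30:90, 1)
    s <- random_na_sequence(L)
    k <- sample(L - 1, 1)
    rot <- paste0(substr(s, k + 1, L), substr(s, 1, k))
    p1 <- sort(vapply(find_sorfs_circular("a", s, min_pep = 1, max_pep = NULL),
                      `[[`, character(1), "peptide"))
    p2 <- sort(vapply(find_sorfs_circular("a", rot, min_pep = 1, max_pep = NULL),
                      `[[`, character(1), "peptide"))
    expect_identical(p1, p2)
  }
})

test_that("multiple-of-3 circles without internal stops cross the junction at most once", {
  set.seed(19)
  for (i in 1:10) {
    L <- sample(10:40, 1) * 3L
    s <- random_na_sequence(L)
    for (r in find_sorfs_circular("c", s, min_pep = 1, max_pep = NULL)) {
      if (!r$terminated) expect_lte(r$junction_crossings, 1L)
    }
  }
})

test_that("ORF names are unique within a run", {
  r <- find_sorfs_linear("t", "ATGAAATAG", min_pep = 1)
  two <- c(r, r)
  nm <- sorf_names(two)
  expect_equal(nm[2], paste0(nm[1], "_2"))
  expect_equal(anyDuplicated(nm), 0L)
})
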