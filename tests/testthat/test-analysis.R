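test_that("closed-form physicochemical values are reproduced", {
  gg <- annotate_properties("GG")
  # one basic (N-terminus 8.6) + one acidic (C-terminus 3.6) group:
  # pI is the midpoint
  expect_equal(gg$pI, (3.6 + 8.6) / 2, tolerance = 1e-3 / 6.1)
  expect_equal(gg$instability, 5 * 13.34)   # (10/2) * DIWV(G,G)

  wy <- annotate_properties("WY")
  expect_equal(wy$ext_reduced, 5500 + 1490)
  expect_equal(wy$ext_cystines, 6990)  # one Cys pair needs two C

  cc <- annotate_properties("CC")
  expect_equal(cc$ext_cystines - cc$ext_reduced, 125)

  ag <- annotate_properties("AG")
  expect_equal(ag$gravy, (1.8 + (-0.4)) / 2)

  expect_equal(annotate_properties("FWYA")$aromaticity, 0.75)
})

test_that("the net-charge model is monotone and vanishes at the pI", {
  set.seed(31)
  for (i in 1:10) {
    s <- random_protein_sequence(sample(10:120, 1))
    pi_ <- isoelectric_point(s)
    expect_lt(abs(net_charge(s, pi_)), 1e-4)
    phs <- sort(stats::runif(6, 0, 14))
    charges <- vapply(phs, function(p) net_charge(s, p), numeric(1))
    expect_true(all(diff(charges) < 0))
  }
  # peptides with no ionizable side chains keep the two-group closed form
  for (len in c(2, 5, 17)) {
    s <- paste(rep("G", len), collapse = "")
    expect_equal(isoelectric_point(s), 6.1, tolerance = 1e-3 / 6.1)
  }
})

test_that("property reports respect their structural invariants", {
  set.seed(32)
  for (e in random_proteome(10, len_range = c(20L, 150L))) {
    p <- annotate_properties(e)
    expect_equal(sum(unlist(p$composition)), p$length)
    expect_gte(p$aromaticity, 0); expect_lte(p$aromaticity, 1)
    expect_gte(p$ext_cystines, p$ext_reduced)
    expect_equal(sum(unlist(p$grouped_composition)), 1, tolerance = 1e-9)
    expect_equal(p$physiological_charge, net_charge(e$sequence, 7.4))
  }
  # nonstandard residues excluded from the numeric models, with a warning
  expect_warning(px <- annotate_properties("GXG"),
                 class = "seqdbkit_nonstandard_residue")
  expect_equal(px$mol_weight, annotate_properties("GG")$mol_weight)
  expect_equal(sum(unlist(px$composition)), 3)
})

test_that("motif counting is overlapping and matches the naive scan", {
  expect_equal(unname(count_motifs("AAAA", "AA")), 3L)
  expect_equal(unname(count_motifs("NASNGS", "Nx[ST]")), 2L)
  expect_equal(unname(count_motifs("ACD", "ACDEF")), 0L)
  expect_error(count_motifs("ACD", "A[ST"), class = "seqdbkit_bad_pattern")
  expect_error(count_motifs("ACD", ""), class = "seqdbkit_bad_pattern")

  set.seed(33)
  for (i in 1:20) {
    s <- random_protein_sequence(sample(20:200, 1))
    pat <- random_protein_sequence(sample(1:4, 1))
    expect_equal(unname(count_motifs(s, pat)), oracle_motif_count(s, pat))
  }
})

test_that("sequence windows have fixed width and pad beyond the termini", {
  e <- protein_entry("a", "MKT")
  w <- sequence_windows(e, data.frame(accession = "a", site = 1), flank = 2)
  expect_equal(w$window, "--MKT")

  e2 <- protein_entry("b", "ABCDEFG")
  w2 <- sequence_windows(e2, data.frame(accession = "b", site = 4), flank = 2)
  expect_equal(w2$window, "BCDEF")

  # peptide mode centers on the first residue of each occurrence
  w3 <- sequence_windows(list(e2), "CDE", flank = 1)
  expect_equal(w3$window, "BCD")
  expect_equal(w3$center, 3L)

  expect_warning(w4 <- sequence_windows(list(e2), "WWW", flank = 1),
                 class = "seqdbkit_peptide_not_found")
  expect_equal(w4$window, "")

  expect_error(sequence_windows(e2, data.frame(accession = "b", site = 99)),
               class = "seqdbkit_site_out_of_range")
  expect_error(sequence_windows(e2, data.frame(accession = "zz", site = 1)),
               class = "seqdbkit_accession_not_found")

  # window width is constant regardless of boundary effects
  set.seed(34)
  for (i in 1:12) {
    s <- random_protein_sequence(sample(5:50, 1))
    ee <- protein_entry("w", s)
    flank <- sample(1:9, 1)
    site <- sample(nchar(s), 1)
    w <- sequence_windows(ee, data.frame(accession = "w", site = site), flank = flank)
    expect_equal(nchar(w$window), 2L * flank + 1L)
  }
})
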