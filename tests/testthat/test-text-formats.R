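test_that("FASTA reading handles wrapping, CRLF, blanks and degenerate records", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACD", "EFG"), path)
  e <- read_fasta(path)
  expect_length(e, 1)
  expect_equal(e[[1]]$sequence, "ACDEFG")

  # CRLF + blank lines
  writeBin(charToRaw(">b desc\r\nAC\r\n\r\nDE\r\n"), path)
  e <- read_fasta(path)
  expect_equal(e[[1]]$sequence, "ACDE")
  expect_equal(e[[1]]$description, "desc")

  writeLines(c(">a", ">b", "AC"), path)
  expect_error(read_fasta(path), class = "seqdbkit_empty_record")

  writeLines(c("ACGT", "more"), path)
  expect_error(read_fasta(path), class = "seqdbkit_not_fasta")
})

test_that("FASTA write/read round-trips random entries and agrees with Biostrings", {
  set.seed(11)
  entries <- random_proteome(60, len_range = c(10L, 200L), with_features = FALSE)
  path <- tempfile(fileext = ".fasta")
  write_fasta(entries, path, wrap = 60)
  back <- read_fasta(path)
  expect_equal(vapply(back, `[[`, character(1), "sequence"),
               vapply(entries, `[[`, character(1), "sequence"))
  expect_equal(vapply(back, `[[`, character(1), "accession"),
               vapply(entries, `[[`, character(1), "accession"))
  # independent reader sees the same residues
  bs <- Biostrings::readAAStringSet(path)
  expect_equal(unname(as.character(bs)),
               vapply(entries, `[[`, character(1), "sequence"))

  # wrap = 0 writes single-line sequences
  write_fasta(entries[1], path, wrap = 0)
  expect_length(readLines(path), 2L)
})

test_that("duplicate-accession policies behave on ingest", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">x", "ACDE", ">x", "GGGG"), path)
  expect_error(read_fasta(path), class = "seqdbkit_duplicate_accession")
  expect_length(read_fasta(path, on_duplicate = "skip"), 1)
  suf <- read_fasta(path, on_duplicate = "suffix")
  expect_equal(vapply(suf, `[[`, character(1), "accession"), c("x", "x_2"))
})

test_that("PEFF tag parsing matches the hand-parsed grammar and inverts", {
  tags <- parse_peff_tags("\\PName=Test protein \\Length=10 \\VariantSimple=(3|A)(5|T)")
  expect_equal(vapply(tags, `[[`, character(1), "key"),
               c("PName", "Length", "VariantSimple"))
  expect_equal(tags[[1]]$values, list("Test protein"))
  expect_equal(tags[[2]]$values, list("10"))
  expect_equal(tags[[3]]$values, list(c("3", "A"), c("5", "T")))

  proc <- parse_peff_tags("\\Processed=(1|22|signal peptide)")
  expect_equal(proc[[1]]$values, list(c("1", "22", "signal peptide")))

  expect_equal(parse_peff_tags(""), list())
  expect_error(parse_peff_tags("\\Bad=(1|2"), class = "seqdbkit_malformed_tag")
  expect_error(parse_peff_tags("\\=x"), class = "seqdbkit_malformed_tag")

  # format o parse is the identity on the model
  for (s in c("\\PName=Test protein \\Length=10 \\VariantSimple=(3|A)(5|T)",
              "\\Processed=(1|22|signal peptide)(23|99|mature protein)",
              "\\ModRes=(5|5|Phosphoserine)")) {
    t1 <- parse_peff_tags(s)
    expect_identical(parse_peff_tags(format_peff_tags(t1)), t1)
  }
})

test_that("PEFF files round-trip metadata, tags and features", {
  path <- tempfile(fileext = ".peff")
  writeLines(c("# PEFF 1.0", "# DbName=toy", "# //",
               ">gen:A \\Length=3", "ACD"), path)
  peff <- read_peff(path)
  expect_equal(peff$meta$extra$DbName, "toy")
  expect_length(peff$entries, 1)
  expect_equal(nchar(peff$entries[[1]]$sequence), 3L)

  # featured round-trip
  set.seed(3)
  entries <- random_proteome(20)
  meta <- database_meta("toy2", "9", db_source = "custom")
  write_peff(meta, entries, path)
  back <- read_peff(path)
  expect_equal(back$meta$db_name, "toy2")
  expect_equal(back$meta$db_version, "9")
  expect_length(back$entries, 20)
  for (i in seq_along(entries)) {
    expect_equal(back$entries[[i]]$accession, entries[[i]]$accession)
    expect_equal(back$entries[[i]]$sequence, entries[[i]]$sequence)
    got <- lapply(back$entries[[i]]$features, function(f) f[c("kind", "start", "end")])
    want <- lapply(entries[[i]]$features, function(f) f[c("kind", "start", "end")])
    expect_equal(got[order(vapply(got, function(x) paste(x, collapse = "|"), ""))],
                 want[order(vapply(want, function(x) paste(x, collapse = "|"), ""))])
  }

  # write(read(f)) is stable once canonicalized
  first <- readLines(path)
  rt <- read_peff(path)
  write_peff(rt$meta, rt$entries, path)
  expect_equal(sort(readLines(path)), sort(first))

  fasta <- tempfile(fileext = ".fasta")
  writeLines(c(">x", "ACDE"), fasta)
  expect_error(read_peff(fasta), class = "seqdbkit_not_peff")
})

test_that("format detection is content-based and reports recoverable issues", {
  p <- tempfile()
  writeLines(c(">x", "ACDE"), p)
  expect_equal(detect_format(p)$format, "fasta")
  expect_length(detect_format(p)$issues, 0)

  writeLines(c("PEPTIDE", "SEQ"), p)
  expect_equal(detect_format(p)$format, "peptide_list")

  writeLines(c(">x", "ACDE", ">x", "GGG"), p)
  res <- detect_format(p)
  expect_equal(res$format, "fasta")
  expect_true(any(grepl("duplicate accession x", res$issues)))

  writeLines(c("# PEFF 1.0", "# //", ">gen:A \\Length=2", "AC"), p)
  expect_equal(detect_format(p)$format, "peff")

  s <- entry_set(c("A", "B"), db_name = "toy")
  write_set(s, p)
  expect_equal(detect_format(p)$format, "set")

  writeLines('{"hello": 1}', p)
  expect_equal(detect_format(p)$format, "unknown")

  db <- tempfile(fileext = ".sqpd")
  h <- create_sqpd(db, database_meta("d", "1"))
  close_sqpd(h)
  expect_equal(detect_format(db)$format, "sqpd")

  expect_error(detect_format(tempfile()), class = "seqdbkit_file_unreadable")
})

test_that("peptide lists read with comments and validation", {
  p <- tempfile()
  writeLines(c("# a comment", "PEPTIDE", "", "seq  "), p)
  expect_equal(read_peptide_list(p), c("PEPTIDE", "SEQ"))
  writeLines("PEP1TIDE", p)
  expect_error(read_peptide_list(p), class = "seqdbkit_illegal_character")
})
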