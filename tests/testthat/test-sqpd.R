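test_that("SQPD create/open round-trips metadata and carries the SQLite magic", {
  path <- tempfile(fileext = ".sqpd")
  meta <- database_meta("toy", "2", db_source = "uniprot",
                        extra = list(Comment = "fixture"))
  h <- create_sqpd(path, meta)
  close_sqpd(h)

  h2 <- open_sqpd(path)
  m <- sqpd_meta(h2)
  expect_equal(m$db_name, "toy")
  expect_equal(m$db_version, "2")
  expect_equal(m$db_source, "uniprot")
  expect_equal(m$n_entries, 0L)
  expect_equal(m$extra$Comment, "fixture")
  close_sqpd(h2)

  expect_equal(rawToChar(readBin(path, "raw", 15)), "SQLite format 3")
  expect_error(create_sqpd(path, meta), class = "seqdbkit_path_exists")
  expect_error(database_meta(""), class = "seqdbkit_invalid_meta")
})

test_that("adding entries stores length and mass and get_entry round-trips", {
  fix <- make_fixture_db(n = 15, seed = 5)
  h <- fix$handle
  expect_equal(sqpd_n_entries(h), 15L)
  expect_equal(sqpd_meta(h)$n_entries, 15L)

  for (e in fix$entries[c(1, 7, 15)]) {
    back <- get_entry(h, e$accession)
    expect_identical(back$sequence, e$sequence)
    expect_equal(length(back$features), length(e$features))
    expect_equal(lapply(back$features, `[`, c("kind", "start", "end", "payload")),
                 lapply(e$features, `[`, c("kind", "start", "end", "payload")))
    expect_equal(back$meta$GN, e$meta$GN)
  }
  expect_error(get_entry(h, "NOPE"), class = "seqdbkit_accession_not_found")

  # single glycine: residue mass + water
  add_entries(h, list(protein_entry("GLY1", "G")))
  row <- DBI::dbGetQuery(h$con, "SELECT length, mass FROM entries WHERE accession='GLY1'")
  expect_equal(row$length, 1L)
  expect_equal(row$mass, 75.07, tolerance = 0.01 / 75.07)
  close_sqpd(h)
})

test_that("a failing batch rolls back atomically", {
  fix <- make_fixture_db(n = 5, seed = 6)
  h <- fix$handle
  n0 <- sqpd_n_entries(h)
  batch <- list(protein_entry("NEW1", "ACDEF"),
                protein_entry(fix$entries[[1]]$accession, "GGGG"))
  expect_error(add_entries(h, batch), class = "seqdbkit_duplicate_accession")
  expect_equal(sqpd_n_entries(h), n0)
  expect_equal(sqpd_meta(h)$n_entries, n0)
  expect_error(get_entry(h, "NEW1"), class = "seqdbkit_accession_not_found")
  close_sqpd(h)
})

test_that("query_entries equals the brute-force filter and uses SQL predicates", {
  fix <- make_fixture_db(n = 40, seed = 7)
  h <- fix$handle
  entries <- fix$entries
  lens <- vapply(entries, function(e) nchar(e$sequence), integer(1))
  accs <- vapply(entries, `[[`, character(1), "accession")

  got <- query_entries(h, length_range = c(50, 150))
  expect_equal(got, sort(accs[lens >= 50 & lens <= 150]))

  has_signal <- vapply(entries, function(e)
    any(vapply(e$features, `[[`, character(1), "kind") == "SIGNAL"), logical(1))
  expect_equal(query_entries(h, feature_key = "SIGNAL"), sort(accs[has_signal]))

  masses <- vapply(entries, function(e) average_mass(e$sequence), numeric(1))
  expect_equal(query_entries(h, mass_range = c(10000, 20000)),
               sort(accs[masses >= 10000 & masses <= 20000]))

  expect_equal(query_entries(h, accessions = accs[c(3, 1)]), sort(accs[c(1, 3)]))

  # random access goes through the accession index, not a table scan
  plan <- DBI::dbGetQuery(h$con,
    "EXPLAIN QUERY PLAN SELECT * FROM entries WHERE accession = 'X'")
  expect_true(any(grepl("USING INDEX", plan$detail, ignore.case = TRUE)))
  close_sqpd(h)
})

test_that("UniProt feature cells parse per the published TSV grammar", {
  f <- parse_feature_cell('SIGNAL 1..22; /evidence="ECO:0000255"')
  expect_length(f, 1)
  expect_equal(f[[1]]$kind, "SIGNAL")
  expect_equal(c(f[[1]]$start, f[[1]]$end), c(1L, 22L))

  v <- parse_feature_cell('VARIANT 54; /note="A -> T"')
  expect_equal(v[[1]]$kind, "VARIANT")
  expect_equal(c(v[[1]]$start, v[[1]]$end), c(54L, 54L))
  expect_equal(v[[1]]$payload, "T")

  expect_equal(parse_feature_cell(""), list())

  multi <- parse_feature_cell(
    'CHAIN 1..50; /note="Chain A"; CHAIN 51..90; /note="Chain B"')
  expect_length(multi, 2)
  expect_equal(multi[[2]]$start, 51L)
  expect_equal(multi[[2]]$payload, "Chain B")

  expect_warning(got <- parse_feature_cell("SIGNAL <1..22"),
                 class = "seqdbkit_uncertain_position")
  expect_length(got, 0)

  row <- list("Signal peptide" = "SIGNAL 1..19",
              "Natural variant" = 'VARIANT 5; /note="G -> R"',
              "Modified residue" = 'MOD_RES 7; /note="Phosphoserine"')
  feats <- map_uniprot_features(row)
  expect_equal(vapply(feats, `[[`, character(1), "kind"),
               c("SIGNAL", "VARIANT", "MOD_RES"))
  expect_equal(feats[[3]]$payload, "Phosphoserine")
})

test_that("feature <-> PEFF tag mapping is inverse on the controlled terms", {
  feats <- list(feature("SIGNAL", 1, 22), feature("CHAIN", 23, 99),
                feature("VARIANT", 54, payload = "T"),
                feature("MOD_RES", 7, payload = "Phosphoserine"))
  tags <- features_to_peff_tags(feats)
  keys <- vapply(tags, `[[`, character(1), "key")
  expect_setequal(keys, c("Processed", "VariantSimple", "ModRes"))
  proc <- tags[[which(keys == "Processed")]]
  expect_equal(proc$values[[1]], c("1", "22", "signal peptide"))
  expect_equal(proc$values[[2]], c("23", "99", "mature protein"))
  vs <- tags[[which(keys == "VariantSimple")]]
  expect_equal(vs$values[[1]], c("54", "T"))

  back <- peff_tags_to_features(tags)
  expect_equal(lapply(back, `[`, c("kind", "start", "end", "payload")),
               lapply(feats, `[`, c("kind", "start", "end", "payload")))

  expect_equal(features_to_peff_tags(list()), list())
})

test_that("FASTA+table -> SQPD -> PEFF -> SQPD preserves every feature triple", {
  set.seed(21)
  entries <- random_proteome(25)
  tab <- synthetic_annotation_table(entries)
  dir <- tempfile("rt"); dir.create(dir)
  fasta <- file.path(dir, "in.fasta")
  tsv <- file.path(dir, "in.tsv")
  write_fasta(entries, fasta, dialect = "generic")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  sq1 <- file.path(dir, "a.sqpd"); peff <- file.path(dir, "a.peff")
  sq2 <- file.path(dir, "b.sqpd")
  fasta_to_sqpd(fasta, sq1, table_path = tsv, db_name = "rt")
  sqpd_to_peff(sq1, peff)
  peff_to_sqpd(peff, sq2)

  h <- open_sqpd(sq2)
  on.exit(close_sqpd(h))
  fingerprint <- function(e) {
    feats <- sapply(e$features, function(f)
      paste(f$kind, f$start, f$end, f$payload, sep = ":"))
    paste(e$accession, e$sequence, paste(sort(unlist(feats)), collapse = ";"))
  }
  for (e in entries) {
    back <- get_entry(h, e$accession)
    expect_identical(fingerprint(back), fingerprint(e))
  }
})
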