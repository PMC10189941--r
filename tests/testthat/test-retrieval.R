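# Canned taxonomy/proteome payloads mirroring each source's response shape;
# taxon 10090 is Mus musculus.

uniprot_tax_payload <- paste(
  "Taxon Id\tScientific name\tCommon name",
  "10090\tMus musculus\thouse mouse",
  "10091\tMus musculus castaneus\t",
  sep = "\n")

ncbi_tax_payload <- '[{"taxid": 10090, "scientificname": "Mus musculus", "commonname": "house mouse"}]'
ensembl_tax_payload <- '[{"id": 10090, "scientific_name": "Mus musculus", "common_name": "house mouse"}]'

fixture_fasta <- paste(
  ">sp|P00001|A_MOUSE Prot A OS=Mus musculus OX=10090 GN=A1 PE=1 SV=1",
  "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", "APILSRVGDGTQDNLSGAEKAVQ",
  ">sp|P00002|B_MOUSE Prot B OS=Mus musculus OX=10090 GN=B1 PE=1 SV=2",
  "MSSHEGGKKKALKQPKKQAKEM",
  ">sp|P00003|C_MOUSE Prot C OS=Mus musculus OX=10090 GN=C1 PE=2 SV=1",
  "MGDVEKGKKIFIMKCSQCHTVEK",
  sep = "\n")

test_that("species search parses each source's payload into taxon hits", {
  for (case in list(list(src = "uniprot", body = uniprot_tax_payload),
                    list(src = "ncbi", body = ncbi_tax_payload),
                    list(src = "ensembl", body = ensembl_tax_payload))) {
    transport <- function(request) list(status = 200L, body = case$body)
    hits <- search_species("mouse", source = case$src, transport = transport)
    expect_true(10090 %in% hits$taxon_id)
    expect_true("Mus musculus" %in% hits$scientific_name)
    expect_equal(unique(hits$source), case$src)
  }
})

test_that("species search rejects bad input and failing transports", {
  expect_error(search_species("", "uniprot"), class = "seqdbkit_invalid_argument")
  t500 <- function(request) list(status = 500L, body = "")
  expect_error(search_species("mouse", "uniprot", transport = t500),
               class = "seqdbkit_transport_error")
  tempty <- function(request) list(status = 200L, body = "")
  expect_equal(nrow(search_species("nothing", "uniprot", transport = tempty)), 0L)
})

test_that("proteome fetch returns raw payloads; only UniProt carries a table", {
  tab <- "Entry\tGene Names\tSignal peptide\nP00001\tA1\tSIGNAL 1..10\n"
  transport <- function(request) {
    body <- if (identical(request$query$format, "tsv")) tab else fixture_fasta
    list(status = 200L, body = body)
  }
  res <- fetch_proteome(10090, "uniprot", transport = transport)
  expect_length(read_fasta(as_tempfile(res$fasta)), 3)
  expect_true(grepl("Signal peptide", res$table))

  res2 <- fetch_proteome(10090, "ncbi", transport = function(request)
    list(status = 200L, body = fixture_fasta))
  expect_null(res2$table)

  expect_error(fetch_proteome(-1, "uniprot"), class = "seqdbkit_invalid_argument")
  expect_error(fetch_proteome(10090, "uniprot", transport = function(request)
    list(status = 200L, body = "")), class = "seqdbkit_empty_result")

  # the UniProt table request asks for the proteoform feature columns
  seen <- list()
  spy <- function(request) {
    seen[[length(seen) + 1L]] <<- request
    list(status = 200L, body = if (identical(request$query$format, "tsv")) tab
                               else fixture_fasta)
  }
  fetch_proteome(10090, "uniprot", transport = spy)
  tsv_req <- Filter(function(r) identical(r$query$format, "tsv"), seen)[[1]]
  expect_true(grepl("ft_signal", tsv_req$query$fields))
  expect_true(grepl("ft_variant", tsv_req$query$fields))
})

test_that("db_manage keeps the seqdbs layout with atomic registration", {
  root <- tempfile("seqdbs"); dir.create(root)
  fasta <- tempfile(fileext = ".fasta")
  writeLines(strsplit(fixture_fasta, "\n")[[1]], fasta)

  db_manage(root, "register", db_name = "mouse", version = "v1", fasta_path = fasta)
  expect_true(dir.exists(file.path(root, "mouse", "v1", "classic")))
  expect_true(dir.exists(file.path(root, "mouse", "v1", "next")))
  h <- open_sqpd(file.path(root, "mouse", "v1", "next", "mouse.sqpd"))
  expect_equal(sqpd_n_entries(h), 3L)
  close_sqpd(h)

  expect_error(db_manage(root, "register", db_name = "mouse", version = "v1",
                         fasta_path = fasta), class = "seqdbkit_version_exists")

  db_manage(root, "register", db_name = "mouse", version = "v2", fasta_path = fasta)
  listing <- db_manage(root, "list")
  expect_equal(nrow(listing), 2L)
  expect_setequal(listing$version, c("v1", "v2"))

  # failed registration leaves nothing behind
  bad <- tempfile(fileext = ".fasta")
  writeLines(c(">x", ">x", "AC"), bad)
  expect_error(db_manage(root, "register", db_name = "broken", version = "v1",
                         fasta_path = bad))
  expect_false(dir.exists(file.path(root, "broken")))
  expect_length(list.files(root, pattern = "staging"), 0L)

  db_manage(root, "delete", db_name = "mouse", version = "v1")
  expect_error(db_manage(root, "delete", db_name = "mouse", version = "v1"),
               class = "seqdbkit_unknown_db")
})
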