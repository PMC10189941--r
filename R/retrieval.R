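# Species lookup and proteome retrieval. All network logic goes through an
# injectable transport: a function taking a request description
# list(url, query = named list) and returning list(status, body). Given the
# transport's output, every function here is pure, so the whole module is
# testable offline with canned payloads. Endpoint URLs are configuration,
# not code constants.

.default_endpoints <- list(
  uniprot_taxonomy = "https://rest.uniprot.org/taxonomy/search",
  uniprot_proteome = "https://rest.uniprot.org/uniprotkb/stream",
  ncbi_taxonomy = "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/esummary.fcgi",
  ncbi_protein = "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
  ensembl_taxonomy = "https://rest.ensembl.org/taxonomy/name",
  ensembl_fasta = "https://ftp.ensembl.org/pub/current_fasta"
)

# UniProt annotation-table columns requested for proteoform-aware SQPD
# construction: identity/naming columns plus the feature columns consumed
# by map_uniprot_features().
UNIPROT_TABLE_FIELDS <- c(
  "accession", "gene_names", "protein_name", "organism_name", "organism_id",
  "ft_signal", "ft_chain", "ft_propep", "ft_transit", "ft_init_met",
  "ft_variant", "ft_mod_res", "ft_conflict"
)

#' Load endpoint configuration
#'
#' Reads a `key=value` or JSON config file and merges it over the built-in
#' endpoint defaults, so endpoint drift never requires a code change.
#'
#' @param path Config file path, or `NULL` for the defaults.
#' @return Named list of endpoint URLs.
#' @export
load_endpoints <- function(path = NULL) {
  eps <- .default_endpoints
  if (is.null(path)) return(eps)
  if (!file.exists(path)) sdk_stop("file_unreadable", paste("no such config:", path))
  txt <- readLines(path, warn = FALSE)
  if (any(grepl("^\\s*\\{", txt))) {
    user <- jsonlite::fromJSON(paste(txt, collapse = "\n"), simplifyVector = TRUE)
  } else {
    txt <- trimws(txt[!grepl("^\\s*(#|$)", txt)])
    kv <- strsplit(txt, "=", fixed = TRUE)
    user <- stats::setNames(lapply(kv, function(x) paste(x[-1], collapse = "=")),
                            vapply(kv, `[[`, character(1), 1L))
  }
  eps[names(user)] <- user
  eps
}

#' Default HTTP transport
#'
#' Performs a plain GET with base R connections. Tests and offline runs
#' should inject a canned transport instead (see [file_transport()]).
#'
#' @return A transport function.
#' @export
http_transport <- function() {
  function(request) {
    url <- request$url
    if (length(request$query)) {
      qs <- paste(vapply(names(request$query), function(k)
        paste0(utils::URLencode(k, reserved = TRUE), "=",
               utils::URLencode(as.character(request$query[[k]]), reserved = TRUE)),
        character(1)), collapse = "&")
      url <- paste0(url, "?", qs)
    }
    body <- tryCatch(paste(readLines(url, warn = FALSE), collapse = "\n"),
                     error = function(e) NULL)
    if (is.null(body)) list(status = 599L, body = "")
    else list(status = 200L, body = body)
  }
}

#' Transport serving a canned payload from a file
#'
#' @param path File whose contents become the response body.
#' @param status HTTP status to report (default 200).
#' @return A transport function ignoring the request.
#' @export
file_transport <- function(path, status = 200L) {
  force(path); force(status)
  function(request) {
    list(status = status, body = paste(readLines(path, warn = FALSE), collapse = "\n"))
  }
}

#' Transport serving in-memory payloads keyed by URL substring
#'
#' @param payloads Named list: name (matched against the request URL) ->
#'   body string.
#' @param status HTTP status to report.
#' @return A transport function.
#' @export
canned_transport <- function(payloads, status = 200L) {
  force(payloads); force(status)
  function(request) {
    for (key in names(payloads)) {
      if (grepl(key, request$url, fixed = TRUE))
        return(list(status = status, body = payloads[[key]]))
    }
    list(status = 404L, body = "")
  }
}

.check_response <- function(resp) {
  if (!is.list(resp) || is.null(resp$status))
    sdk_stop("transport_error", "transport returned no status")
  if (resp$status != 200L)
    sdk_stop("transport_error", paste("transport returned status", resp$status))
  resp$body %||% ""
}

#' Search a taxonomy for a species
#'
#' Queries the source's taxonomy service (through the transport) and
#' parses the payload into species hits. Payload grammars: UniProt returns
#' TSV with `Taxon Id`, `Scientific name`, `Common name` columns; NCBI and
#' Ensembl return JSON arrays of objects with taxon id and name keys.
#'
#' @param query Non-empty species name fragment.
#' @param source `"uniprot"`, `"ncbi"` or `"ensembl"`.
#' @param transport A transport function (defaults to live HTTP).
#' @param endpoints Endpoint list from [load_endpoints()].
#' @return A data.frame of hits: `taxon_id`, `scientific_name`,
#'   `common_name`, `source`. Zero rows is a valid "no hits" result.
#' @export
search_species <- function(query, source = c("uniprot", "ncbi", "ensembl"),
                           transport = http_transport(),
                           endpoints = load_endpoints()) {
  source <- match.arg(source)
  if (!is_string(query) || !nzchar(trimws(query)))
    sdk_stop("invalid_argument", "query must be non-empty")
  url <- endpoints[[paste0(source, "_taxonomy")]]
  body <- .check_response(transport(list(url = url, query = list(query = query))))
  hits <- switch(source,
    uniprot = .parse_uniprot_taxonomy(body),
    ncbi = .parse_json_taxonomy(body, id_key = "taxid",
                                sci_key = "scientificname", com_key = "commonname"),
    ensembl = .parse_json_taxonomy(body, id_key = "id",
                                   sci_key = "scientific_name", com_key = "common_name")
  )
  if (nrow(hits)) {
    if (any(hits$taxon_id <= 0L)) sdk_stop("transport_error", "non-positive taxon id in payload")
    hits$source <- source
  }
  hits
}

.species_hits <- function(taxon_id = integer(), scientific_name = character(),
                          common_name = character()) {
  data.frame(taxon_id = as.integer(taxon_id),
             scientific_name = as.character(scientific_name),
             common_name = as.character(common_name),
             source = character(length(taxon_id)),
             stringsAsFactors = FALSE)
}

.parse_uniprot_taxonomy <- function(body) {
  if (!nzchar(trimws(body))) return(.species_hits())
  df <- utils::read.delim(text = body, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  id_col <- grep("^Taxon", names(df), value = TRUE)[1]
  if (is.na(id_col)) sdk_stop("transport_error", "taxonomy payload lacks a Taxon Id column")
  .species_hits(df[[id_col]], df[["Scientific name"]] %||% rep("", nrow(df)),
                df[["Common name"]] %||% rep("", nrow(df)))
}

.parse_json_taxonomy <- function(body, id_key, sci_key, com_key) {
  if (!nzchar(trimws(body))) return(.species_hits())
  obj <- jsonlite::fromJSON(body, simplifyDataFrame = TRUE)
  if (!length(obj)) return(.species_hits())
  .species_hits(obj[[id_key]], obj[[sci_key]],
                if (!is.null(obj[[com_key]])) obj[[com_key]] else rep("", NROW(obj)))
}

#' Download a species-specific proteome
#'
#' Returns the raw FASTA payload unmodified, plus (UniProt only) the
#' annotation table whose columns include every feature column needed for
#' proteoform-aware SQPD construction. NCBI/Ensembl sources return no
#' table, which downstream leads to a featureless SQPD unless the user
#' supplies a table.
#'
#' @param taxon_id Positive taxon identifier.
#' @param source `"uniprot"`, `"ncbi"` or `"ensembl"`.
#' @param reviewed_only,isoforms UniProt options.
#' @param transport,endpoints See [search_species()].
#' @return `list(fasta = <string>, table = <string or NULL>)`.
#' @export
fetch_proteome <- function(taxon_id, source = c("uniprot", "ncbi", "ensembl"),
                           reviewed_only = TRUE, isoforms = FALSE,
                           transport = http_transport(),
                           endpoints = load_endpoints()) {
  source <- match.arg(source)
  taxon_id <- as.integer(taxon_id)
  if (is.na(taxon_id) || taxon_id <= 0L)
    sdk_stop("invalid_argument", "taxon_id must be a positive integer")
  if (source == "uniprot") {
    q <- paste0("organism_id:", taxon_id,
                if (reviewed_only) " AND reviewed:true" else "")
    fasta <- .check_response(transport(list(
      url = endpoints$uniprot_proteome,
      query = list(query = q, format = "fasta",
                   includeIsoform = tolower(as.character(isoforms))))))
    table <- .check_response(transport(list(
      url = endpoints$uniprot_proteome,
      query = list(query = q, format = "tsv",
                   fields = paste(UNIPROT_TABLE_FIELDS, collapse = ",")))))
    if (!nzchar(trimws(fasta))) sdk_stop("empty_result", "no sequences returned")
    return(list(fasta = fasta, table = table))
  }
  url <- endpoints[[if (source == "ncbi") "ncbi_protein" else "ensembl_fasta"]]
  fasta <- .check_response(transport(list(url = url, query = list(taxon = taxon_id))))
  if (!nzchar(trimws(fasta))) sdk_stop("empty_result", "no sequences returned")
  list(fasta = fasta, table = NULL)
}
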