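# SQPD: a protein sequence database stored as a single SQLite 3.x file whose
# tables mirror PEFF proteoform semantics. Schema (frozen as "sqpd-1"):
#   meta(key TEXT PRIMARY KEY, value TEXT)
#   entries(id INTEGER PRIMARY KEY, prefix TEXT, accession TEXT UNIQUE NOT NULL,
#           description TEXT, sequence TEXT NOT NULL, length INTEGER NOT NULL,
#           mass REAL, meta TEXT)
#   features(id INTEGER PRIMARY KEY, entry_id INTEGER REFERENCES entries(id),
#            key TEXT NOT NULL, start INTEGER, "end" INTEGER, payload TEXT)
# with indices on entries(accession), entries(length), entries(mass),
# features(entry_id) and features(key). The mass column stores the average
# molecular mass so that mass filters never recompute it.

SQPD_SCHEMA_VERSION <- "sqpd-1"

#' Average molecular mass of a peptide
#'
#' Sum of average residue masses plus one water. Residues outside the 20
#' standard letters contribute zero mass.
#'
#' @param seq Amino-acid sequence string.
#' @return Mass in Da.
#' @export
average_mass <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  known <- AA_AVG_MASS[chars]
  sum(known, na.rm = TRUE) + MASS_WATER
}

monoisotopic_mass <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  sum(AA_MONO_MASS[chars], na.rm = TRUE) + MASS_WATER_MONO
}

#' Create a new SQPD database
#'
#' @param path Output path; must not exist unless `overwrite = TRUE`.
#' @param meta A [database_meta()] with non-empty `db_name`/`db_version`.
#' @param overwrite Replace an existing file.
#' @return An open `sqpd_handle`.
#' @export
create_sqpd <- function(path, meta, overwrite = FALSE) {
  if (!inherits(meta, "database_meta")) sdk_stop("invalid_meta", "meta must be a database_meta")
  if (file.exists(path)) {
    if (!overwrite) sdk_stop("path_exists", paste(path, "already exists"))
    unlink(path)
  }
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  ok <- FALSE
  on.exit(if (!ok) DBI::dbDisconnect(con))
  DBI::dbExecute(con, "CREATE TABLE meta (key TEXT PRIMARY KEY, value TEXT)")
  DBI::dbExecute(con, "
    CREATE TABLE entries (
      id INTEGER PRIMARY KEY,
      prefix TEXT,
      accession TEXT UNIQUE NOT NULL,
      description TEXT,
      sequence TEXT NOT NULL,
      length INTEGER NOT NULL,
      mass REAL,
      meta TEXT
    )")
  DBI::dbExecute(con, "
    CREATE TABLE features (
      id INTEGER PRIMARY KEY,
      entry_id INTEGER NOT NULL REFERENCES entries(id) ON DELETE CASCADE,
      key TEXT NOT NULL,
      start INTEGER,
      \"end\" INTEGER,
      payload TEXT
    )")
  for (idx in c("CREATE INDEX idx_entries_accession ON entries(accession)",
                "CREATE INDEX idx_entries_length ON entries(length)",
                "CREATE INDEX idx_entries_mass ON entries(mass)",
                "CREATE INDEX idx_features_entry ON features(entry_id)",
                "CREATE INDEX idx_features_key ON features(key)"))
    DBI::dbExecute(con, idx)

  rows <- data.frame(
    key = c("schema_version", "db_name", "db_version", "db_source",
            "sequence_type", "n_entries", "created"),
    value = c(SQPD_SCHEMA_VERSION, meta$db_name, meta$db_version, meta$db_source,
              meta$sequence_type, "0", meta$created),
    stringsAsFactors = FALSE
  )
  if (length(meta$extra))
    rows <- rbind(rows, data.frame(key = paste0("extra:", names(meta$extra)),
                                   value = unlist(meta$extra, use.names = FALSE)))
  DBI::dbAppendTable(con, "meta", rows)
  ok <- TRUE
  h <- structure(list(path = path, con = con), class = "sqpd_handle")
  h
}

#' Open an existing SQPD database
#'
#' Verifies the schema signature (`schema_version` meta row and the expected
#' tables) before returning a handle.
#'
#' @param path Path to an SQPD file.
#' @return An `sqpd_handle`.
#' @export
open_sqpd <- function(path) {
  if (!file.exists(path)) sdk_stop("file_unreadable", paste("no such file:", path))
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  ok <- FALSE
  on.exit(if (!ok) DBI::dbDisconnect(con))
  tabs <- DBI::dbListTables(con)
  if (!all(c("meta", "entries", "features") %in% tabs))
    sdk_stop("not_sqpd", paste(path, "lacks the SQPD tables"))
  ver <- DBI::dbGetQuery(con, "SELECT value FROM meta WHERE key = 'schema_version'")
  if (!nrow(ver) || !startsWith(ver$value[1], "sqpd-"))
    sdk_stop("not_sqpd", paste(path, "has no sqpd schema_version"))
  ok <- TRUE
  structure(list(path = path, con = con), class = "sqpd_handle")
}

#' Close an SQPD handle
#' @param h An `sqpd_handle`.
#' @export
close_sqpd <- function(h) {
  if (DBI::dbIsValid(h$con)) DBI::dbDisconnect(h$con)
  invisible(NULL)
}

#' Read the database metadata of an SQPD handle
#' @param h An `sqpd_handle`.
#' @return A [database_meta()].
#' @export
sqpd_meta <- function(h) {
  rows <- DBI::dbGetQuery(h$con, "SELECT key, value FROM meta")
  kv <- stats::setNames(rows$value, rows$key)
  extra_keys <- grep("^extra:", rows$key, value = TRUE)
  database_meta(
    db_name = kv[["db_name"]], db_version = kv[["db_version"]],
    db_source = kv[["db_source"]], sequence_type = kv[["sequence_type"]],
    n_entries = as.integer(kv[["n_entries"]]), created = kv[["created"]],
    extra = stats::setNames(as.list(kv[extra_keys]), sub("^extra:", "", extra_keys))
  )
}

#' @export
print.sqpd_handle <- function(x, ...) {
  m <- sqpd_meta(x)
  cat(sprintf("<SQPD %s v%s (%s): %d entries at %s>\n",
              m$db_name, m$db_version, m$db_source, m$n_entries, x$path))
  invisible(x)
}

#' Add entries to an SQPD database
#'
#' Inserts one `entries` row per protein (length and average mass
#' precomputed) and one `features` row per feature, as a single transaction:
#' on any failure the whole batch is rolled back and `n_entries` is
#' unchanged.
#'
#' @param h An open `sqpd_handle`.
#' @param entries List of [protein_entry()] objects.
#' @param on_duplicate `"error"` (default, aborts the batch), `"skip"` or
#'   `"suffix"`.
#' @return Number of entries added, invisibly.
#' @export
add_entries <- function(h, entries, on_duplicate = c("error", "skip", "suffix")) {
  on_duplicate <- match.arg(on_duplicate)
  con <- h$con
  for (e in entries) {
    if (!inherits(e, "protein_entry"))
      sdk_stop("invalid_entry", "entries must be protein_entry objects")
  }
  DBI::dbExecute(con, "BEGIN IMMEDIATE")
  added <- 0L
  tryCatch({
    existing <- DBI::dbGetQuery(con, "SELECT accession FROM entries")$accession
    seen <- new.env(parent = emptyenv())
    for (a in existing) assign(a, 1L, envir = seen)
    keep <- logical(length(entries))
    accs <- character(length(entries))
    for (i in seq_along(entries)) {
      acc <- entries[[i]]$accession
      k <- if (exists(acc, envir = seen)) get(acc, envir = seen) else 0L
      if (k > 0L) {
        if (on_duplicate == "error")
          sdk_stop("duplicate_accession", paste("duplicate accession:", acc))
        if (on_duplicate == "skip") next
        assign(acc, k + 1L, envir = seen)
        acc <- paste0(acc, "_", k + 1L)
      } else assign(acc, 1L, envir = seen)
      keep[i] <- TRUE
      accs[i] <- acc
    }
    batch <- entries[keep]
    if (length(batch)) {
      df <- data.frame(
        prefix = vapply(batch, `[[`, character(1), "prefix"),
        accession = accs[keep],
        description = vapply(batch, `[[`, character(1), "description"),
        sequence = vapply(batch, `[[`, character(1), "sequence"),
        stringsAsFactors = FALSE
      )
      df$length <- nchar(df$sequence)
      df$mass <- vapply(df$sequence, average_mass, numeric(1), USE.NAMES = FALSE)
      df$meta <- vapply(batch, function(e)
        if (length(e$meta)) as.character(jsonlite::toJSON(e$meta, auto_unbox = TRUE))
        else NA_character_, character(1))
      DBI::dbExecute(con,
        "INSERT INTO entries (prefix, accession, description, sequence, length, mass, meta)
         VALUES (?, ?, ?, ?, ?, ?, ?)",
        params = unname(as.list(df[c("prefix", "accession", "description",
                                     "sequence", "length", "mass", "meta")])))
      ids <- DBI::dbGetQuery(con, sprintf(
        "SELECT id, accession FROM entries WHERE accession IN (%s)",
        paste(rep("?", nrow(df)), collapse = ",")),
        params = as.list(df$accession))
      id_of <- stats::setNames(ids$id, ids$accession)
      feats <- list()
      for (i in seq_along(batch)) {
        for (f in batch[[i]]$features) {
          feats[[length(feats) + 1L]] <- data.frame(
            entry_id = id_of[[df$accession[i]]], key = f$kind,
            start = f$start, end = f$end, payload = f$payload,
            stringsAsFactors = FALSE)
        }
      }
      if (length(feats)) {
        fd <- do.call(rbind, feats)
        DBI::dbExecute(con,
          'INSERT INTO features (entry_id, key, start, "end", payload) VALUES (?, ?, ?, ?, ?)',
          params = unname(as.list(fd)))
      }
      added <- nrow(df)
    }
    n <- DBI::dbGetQuery(con, "SELECT COUNT(*) AS n FROM entries")$n[1]
    DBI::dbExecute(con, "UPDATE meta SET value = ? WHERE key = 'n_entries'",
                   params = list(as.character(n)))
    DBI::dbExecute(con, "COMMIT")
  }, error = function(err) {
    DBI::dbExecute(con, "ROLLBACK")
    stop(err)
  })
  invisible(added)
}

.row_to_entry <- function(con, row) {
  feats <- DBI::dbGetQuery(con,
    'SELECT key, start, "end" AS end, payload FROM features WHERE entry_id = ? ORDER BY id',
    params = list(row$id))
  features <- lapply(seq_len(nrow(feats)), function(i)
    feature(feats$key[i], feats$start[i], feats$end[i], payload = feats$payload[i]))
  meta <- if (!is.na(row$meta) && nzchar(row$meta))
    jsonlite::fromJSON(row$meta, simplifyVector = TRUE) else list()
  protein_entry(row$accession, row$sequence, description = row$description %||% "",
                prefix = row$prefix %||% "generic", features = features,
                meta = as.list(meta))
}

#' Fetch one entry by accession
#'
#' Reconstructs the full [protein_entry()] (sequence byte-identical,
#' features included) through the accession index: no other rows are read.
#'
#' @param h An open `sqpd_handle`.
#' @param accession Accession string.
#' @return A [protein_entry()].
#' @export
get_entry <- function(h, accession) {
  row <- DBI::dbGetQuery(h$con,
    "SELECT * FROM entries WHERE accession = ?", params = list(accession))
  if (!nrow(row))
    sdk_stop("accession_not_found", paste("no entry with accession", accession))
  .row_to_entry(h$con, row[1, ])
}

#' Fetch several entries (or all of them)
#'
#' @param h An open `sqpd_handle`.
#' @param accessions Character vector, or `NULL` for every entry in
#'   accession-sorted order.
#' @return List of [protein_entry()] objects.
#' @export
get_entries <- function(h, accessions = NULL) {
  if (is.null(accessions)) {
    rows <- DBI::dbGetQuery(h$con, "SELECT * FROM entries ORDER BY accession")
    return(lapply(seq_len(nrow(rows)), function(i) .row_to_entry(h$con, rows[i, ])))
  }
  lapply(accessions, function(a) get_entry(h, a))
}

#' Query accessions by indexed predicates
#'
#' Evaluates a conjunction of predicates entirely inside SQL (no full scan in
#' application code): length range, mass range, feature-key presence and an
#' accession whitelist.
#'
#' @param h An open `sqpd_handle`.
#' @param length_range,mass_range Numeric `c(lo, hi)` (either bound may be
#'   `NA` for open).
#' @param feature_key Feature kind that must be present (e.g. `"SIGNAL"`).
#' @param accessions Restrict to this accession list.
#' @return Character vector of matching accessions, ascending.
#' @export
query_entries <- function(h, length_range = NULL, mass_range = NULL,
                          feature_key = NULL, accessions = NULL) {
  where <- character(); params <- list()
  add_range <- function(col, rng, where, params) {
    if (!is.na(rng[1])) { where <- c(where, paste(col, ">= ?")); params <- c(params, rng[1]) }
    if (!is.na(rng[2])) { where <- c(where, paste(col, "<= ?")); params <- c(params, rng[2]) }
    list(where, params)
  }
  if (!is.null(length_range)) {
    r <- add_range("length", length_range, where, params); where <- r[[1]]; params <- r[[2]]
  }
  if (!is.null(mass_range)) {
    r <- add_range("mass", mass_range, where, params); where <- r[[1]]; params <- r[[2]]
  }
  if (!is.null(feature_key)) {
    where <- c(where, "EXISTS (SELECT 1 FROM features f WHERE f.entry_id = entries.id AND f.key = ?)")
    params <- c(params, feature_key)
  }
  if (!is.null(accessions)) {
    if (!length(accessions)) return(character())
    where <- c(where, paste0("accession IN (",
                             paste(rep("?", length(accessions)), collapse = ", "), ")"))
    params <- c(params, as.list(accessions))
  }
  sql <- paste("SELECT accession FROM entries",
               if (length(where)) paste("WHERE", paste(where, collapse = " AND ")) else "",
               "ORDER BY accession")
  if (length(params)) DBI::dbGetQuery(h$con, sql, params = params)$accession
  else DBI::dbGetQuery(h$con, sql)$accession
}

#' Number of entries in an SQPD database
#' @param h An open `sqpd_handle`.
#' @return Integer count.
#' @export
sqpd_n_entries <- function(h) {
  DBI::dbGetQuery(h$con, "SELECT COUNT(*) AS n FROM entries")$n[1]
}
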