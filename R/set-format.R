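# SET: a JSON manifest naming a subset of entries of a parent database.
# A SET file carries no sequence text, only the database identity and an
# ordered list of unique accessions, so its size is independent of sequence
# lengths. Frozen key set: {"format":"SET", "set_name", "db_name",
# "db_version", "created", "description", "entries"}.

#' Construct an entry set
#'
#' @param entries Character vector of unique, non-empty accessions (order is
#'   preserved).
#' @param set_name Name of the subset.
#' @param db_name,db_version Identity of the parent database.
#' @param description Free text.
#' @param created ISO-8601 timestamp.
#' @return An object of class `entry_set`.
#' @export
entry_set <- function(entries, set_name = "subset", db_name = "unnamed",
                      db_version = "1", description = "", created = iso_now()) {
  entries <- as.character(entries)
  if (any(!nzchar(entries)) || anyNA(entries))
    sdk_stop("invalid_set", "entries must be non-empty strings")
  if (anyDuplicated(entries))
    sdk_stop("duplicate_entry_in_set",
             paste("duplicate accession in set:", entries[duplicated(entries)][1]))
  structure(
    list(format = "SET", set_name = set_name, db_name = db_name,
         db_version = db_version, created = created,
         description = description, entries = entries),
    class = "entry_set"
  )
}

#' @export
format.entry_set <- function(x, ...) {
  sprintf("<entry_set '%s' (%s v%s): %d accession(s)>",
          x$set_name, x$db_name, x$db_version, length(x$entries))
}

#' @export
print.entry_set <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Write a SET file
#'
#' @param s An [entry_set()].
#' @param path Output path (conventionally `.set` or `.set.json`).
#' @return `path`, invisibly.
#' @export
write_set <- function(s, path) {
  if (!inherits(s, "entry_set")) sdk_stop("invalid_set", "s must be an entry_set")
  obj <- unclass(s)
  obj$entries <- as.list(obj$entries)  # keep a JSON array even for 1 entry
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a SET file
#'
#' @param path Path to a SET JSON file.
#' @return An [entry_set()].
#' @export
read_set <- function(path) {
  if (!file.exists(path)) sdk_stop("file_unreadable", paste("no such file:", path))
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) sdk_stop("not_set", paste("not JSON:", conditionMessage(e))))
  if (!is.list(obj) || !identical(obj[["format"]], "SET"))
    sdk_stop("not_set", paste(path, "lacks the SET signature key"))
  entry_set(
    entries = obj[["entries"]] %||% character(),
    set_name = obj[["set_name"]] %||% "subset",
    db_name = obj[["db_name"]] %||% "unnamed",
    db_version = obj[["db_version"]] %||% "1",
    description = obj[["description"]] %||% "",
    created = obj[["created"]] %||% iso_now()
  )
}

#' Resolve a SET against an SQPD database
#'
#' Yields the named entries in SET order. A `db_name`/`db_version` mismatch
#' between the SET and the database metadata is a warning. Missing
#' accessions follow `on_missing`: `error` aborts, `skip` drops them with a
#' warning, `report` drops them and attaches the missing list as the
#' `"missing"` attribute of the result.
#'
#' @param s An [entry_set()].
#' @param h An open `sqpd_handle`.
#' @param on_missing `"error"`, `"skip"` or `"report"`.
#' @return List of [protein_entry()] objects in SET order.
#' @export
resolve_set <- function(s, h, on_missing = c("error", "skip", "report")) {
  on_missing <- match.arg(on_missing)
  m <- sqpd_meta(h)
  if (!identical(s$db_name, m$db_name) || !identical(s$db_version, m$db_version))
    sdk_warn("set_db_mismatch",
             sprintf("SET targets %s v%s but database is %s v%s",
                     s$db_name, s$db_version, m$db_name, m$db_version))
  present <- query_entries(h, accessions = s$entries)
  missing <- setdiff(s$entries, present)
  if (length(missing) && on_missing == "error")
    sdk_stop("missing_accession",
             paste("accession(s) not in database:", paste(missing, collapse = ", ")))
  if (length(missing))
    sdk_warn("missing_accession",
             paste("skipped missing accession(s):", paste(missing, collapse = ", ")))
  out <- lapply(setdiff(s$entries, missing), function(a) get_entry(h, a))
  if (on_missing == "report") attr(out, "missing") <- missing
  out
}
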