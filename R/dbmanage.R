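# Local sequence-database registry under a "seqdbs" root:
#   seqdbs/<db_name>/<version>/classic/  - FASTA / PEFF / annotation tables
#   seqdbs/<db_name>/<version>/next/     - SQPD / SET
# Registration builds the version in a staging directory and atomically
# renames it into place, so a failed register never leaves a half-built
# version behind.

#' Manage the local sequence-database registry
#'
#' @param seqdbs_root Registry root directory (created on demand).
#' @param action `"register"`, `"update"`, `"list"` or `"delete"`.
#' @param db_name,version Database identity (required except for `list`).
#' @param fasta_path Input FASTA (register/update).
#' @param table_path Optional UniProt-style annotation table; its features
#'   are attached to the SQPD build.
#' @param db_source Source tag recorded in metadata.
#' @param force Allow re-registering an existing version.
#' @return For `list`, a data.frame of `(db_name, version)`; for the other
#'   actions the version directory path, invisibly.
#' @export
db_manage <- function(seqdbs_root, action = c("register", "update", "list", "delete"),
                      db_name = NULL, version = NULL,
                      fasta_path = NULL, table_path = NULL,
                      db_source = "custom", force = FALSE) {
  action <- match.arg(action)
  if (!dir.exists(seqdbs_root)) dir.create(seqdbs_root, recursive = TRUE)

  if (action == "list") {
    dbs <- list.dirs(seqdbs_root, recursive = FALSE, full.names = FALSE)
    rows <- list()
    for (db in dbs) {
      for (v in list.dirs(file.path(seqdbs_root, db), recursive = FALSE,
                          full.names = FALSE)) {
        rows[[length(rows) + 1L]] <- data.frame(db_name = db, version = v,
                                                stringsAsFactors = FALSE)
      }
    }
    return(if (length(rows)) do.call(rbind, rows)
           else data.frame(db_name = character(), version = character(),
                           stringsAsFactors = FALSE))
  }

  if (is.null(db_name) || is.null(version))
    sdk_stop("invalid_argument", paste(action, "needs db_name and version"))
  vdir <- file.path(seqdbs_root, db_name, version)

  if (action == "delete") {
    if (!dir.exists(vdir)) sdk_stop("unknown_db", paste("not registered:", db_name, version))
    unlink(vdir, recursive = TRUE)
    dbdir <- file.path(seqdbs_root, db_name)
    if (!length(list.dirs(dbdir, recursive = FALSE))) unlink(dbdir, recursive = TRUE)
    return(invisible(vdir))
  }

  # register / update
  if (action == "update" && !dir.exists(vdir))
    sdk_stop("unknown_db", paste("not registered:", db_name, version))
  if (action == "register" && dir.exists(vdir) && !force)
    sdk_stop("version_exists", paste(db_name, version, "already registered (use force)"))
  if (is.null(fasta_path)) sdk_stop("invalid_argument", "fasta_path is required")

  entries <- read_fasta(fasta_path)
  if (!is.null(table_path))
    entries <- apply_feature_table(entries, read_annotation_table(table_path))

  staging <- tempfile("seqdbs_staging_", tmpdir = seqdbs_root)
  dir.create(file.path(staging, "classic"), recursive = TRUE)
  dir.create(file.path(staging, "next"), recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(staging, recursive = TRUE))

  file.copy(fasta_path, file.path(staging, "classic", paste0(db_name, ".fasta")))
  if (!is.null(table_path))
    file.copy(table_path, file.path(staging, "classic", paste0(db_name, ".tsv")))
  meta <- database_meta(db_name, version, db_source = db_source)
  h <- create_sqpd(file.path(staging, "next", paste0(db_name, ".sqpd")), meta)
  add_entries(h, entries)
  close_sqpd(h)

  if (dir.exists(vdir)) unlink(vdir, recursive = TRUE)
  dir.create(dirname(vdir), recursive = TRUE, showWarnings = FALSE)
  if (!file.rename(staging, vdir))
    sdk_stop("io_error", paste("could not move staged version into", vdir))
  ok <- TRUE
  invisible(vdir)
}
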