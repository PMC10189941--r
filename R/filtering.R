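# Subset selection. Filters evaluate a conjunction of clauses and emit a
# SET (never sequences), so results stay small and composable.

#' Build a filter specification
#'
#' A filter is a conjunction of clauses `(field, op, value)` with
#' `field` one of `length`, `mass`, `feature_key`, `motif`, `accession_in`
#' or `column:<name>` (annotation-table columns), and `op` one of `ge`,
#' `le`, `between`, `has`, `matches`, `in`. Numeric ops apply only to
#' numeric fields.
#'
#' @param ... Clauses built with [clause()].
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(...) {
  clauses <- list(...)
  if (length(clauses) == 1L && is.list(clauses[[1]]) && !inherits(clauses[[1]], "filter_clause"))
    clauses <- clauses[[1]]
  if (!length(clauses)) sdk_stop("invalid_filter", "a filter needs at least one clause")
  for (cl in clauses)
    if (!inherits(cl, "filter_clause")) sdk_stop("invalid_filter", "clauses must be built with clause()")
  structure(list(clauses = clauses, combine = "and"), class = "filter_spec")
}

#' Build one filter clause
#'
#' @param field Field name (see [filter_spec()]).
#' @param op Operator.
#' @param value Operand: a number for `ge`/`le`, `c(lo, hi)` for `between`,
#'   a feature kind for `has`, a motif pattern for `matches`, a character
#'   vector for `in`.
#' @return A `filter_clause`.
#' @export
clause <- function(field, op = c("ge", "le", "between", "has", "matches", "in"), value) {
  op <- match.arg(op)
  numeric_field <- field %in% c("length", "mass") || startsWith(field, "column:")
  if (op %in% c("ge", "le", "between") && !numeric_field)
    sdk_stop("invalid_filter", sprintf("numeric op '%s' on non-numeric field '%s'", op, field))
  if (op == "between" && (length(value) != 2L || any(is.na(suppressWarnings(as.numeric(value))))))
    sdk_stop("invalid_filter", "'between' needs c(lo, hi)")
  if (op == "between" && as.numeric(value[1]) > as.numeric(value[2]))
    sdk_stop("invalid_filter", "'between' bounds are inverted (lo > hi)")
  structure(list(field = field, op = op, value = value), class = "filter_clause")
}

#' Filter an SQPD database into a SET
#'
#' Evaluates the spec's conjunction over the database. Length, mass,
#' feature and accession clauses are pushed into SQL; motif clauses are
#' evaluated with [count_motifs()] on the SQL-narrowed candidates. The
#' result is an [entry_set()] in ascending accession order carrying the
#' database identity; an empty result is a valid (empty) SET.
#'
#' @param h An open `sqpd_handle`.
#' @param spec A [filter_spec()].
#' @param set_name Name recorded in the resulting SET.
#' @return An [entry_set()].
#' @export
seq_filter <- function(h, spec, set_name = "filtered") {
  if (!inherits(spec, "filter_spec")) sdk_stop("invalid_filter", "spec must be a filter_spec")
  length_range <- NULL; mass_range <- NULL
  feature_keys <- character(); motifs <- character(); acc_lists <- list()
  narrow <- function(range, cl) {
    if (!cl$op %in% c("ge", "le", "between"))
      sdk_stop("invalid_filter", sprintf("field '%s' needs a numeric op", cl$field))
    lo <- if (cl$op == "ge") as.numeric(cl$value[1]) else if (cl$op == "between") as.numeric(cl$value[1]) else NA
    hi <- if (cl$op == "le") as.numeric(cl$value[1]) else if (cl$op == "between") as.numeric(cl$value[2]) else NA
    if (is.null(range)) range <- c(NA_real_, NA_real_)
    if (!is.na(lo)) range[1] <- max(range[1], lo, na.rm = TRUE)
    if (!is.na(hi)) range[2] <- min(range[2], hi, na.rm = TRUE)
    range
  }
  for (cl in spec$clauses) {
    switch(cl$field,
      length = { length_range <- narrow(length_range, cl) },
      mass = { mass_range <- narrow(mass_range, cl) },
      feature_key = {
        if (cl$op != "has") sdk_stop("invalid_filter", "feature_key supports op 'has'")
        feature_keys <- c(feature_keys, cl$value)
      },
      motif = {
        if (cl$op != "matches") sdk_stop("invalid_filter", "motif supports op 'matches'")
        motifs <- c(motifs, cl$value)
      },
      accession_in = {
        if (cl$op != "in") sdk_stop("invalid_filter", "accession_in supports op 'in'")
        acc_lists[[length(acc_lists) + 1L]] <- cl$value
      },
      sdk_stop("unknown_field", paste("unknown filter field:", cl$field))
    )
  }
  accessions <- if (length(acc_lists)) Reduce(intersect, acc_lists) else NULL
  hits <- query_entries(h, length_range = length_range, mass_range = mass_range,
                        feature_key = if (length(feature_keys)) feature_keys[1] else NULL,
                        accessions = accessions)
  # further feature keys and motifs on the narrowed candidates
  for (fk in feature_keys[-1])
    hits <- query_entries(h, feature_key = fk, accessions = hits)
  if (length(motifs) && length(hits)) {
    keep <- vapply(hits, function(a) {
      e <- get_entry(h, a)
      all(vapply(motifs, function(m) count_motifs(e, m)[[1]] > 0L, logical(1)))
    }, logical(1))
    hits <- hits[keep]
  }
  m <- sqpd_meta(h)
  entry_set(sort(hits), set_name = set_name, db_name = m$db_name,
            db_version = m$db_version,
            description = "seq_filter result")
}

#' Filter an annotation table into a SET
#'
#' Applies `column:<name>` clauses to a TSV table. Numeric clauses parse
#' cells leniently: blank or non-numeric cells are excluded from the clause
#' (with a warning) rather than failing the run, but a column with no
#' numeric cells at all is an error for numeric ops. Duplicate ids are
#' deduplicated with a warning.
#'
#' @param table_path Path to a TSV with a header row.
#' @param spec A [filter_spec()] whose clauses use `column:<name>` fields
#'   (plus optionally `accession_in`).
#' @param id_column Name of the identifier column.
#' @param set_name Name recorded in the resulting SET.
#' @return An [entry_set()].
#' @export
tab_filter <- function(table_path, spec, id_column = "Entry", set_name = "filtered") {
  if (!inherits(spec, "filter_spec")) sdk_stop("invalid_filter", "spec must be a filter_spec")
  df <- read_annotation_table(table_path, id_column)
  ids <- df[[id_column]]
  if (anyDuplicated(ids)) {
    sdk_warn("duplicate_id", "duplicate ids in table; keeping first occurrence")
    keep <- !duplicated(ids)
    df <- df[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  mask <- rep(TRUE, nrow(df))
  for (cl in spec$clauses) {
    if (cl$field == "accession_in") {
      mask <- mask & ids %in% cl$value
      next
    }
    if (!startsWith(cl$field, "column:"))
      sdk_stop("unknown_field", paste("tab_filter supports column:<name> fields, got", cl$field))
    colname <- sub("^column:", "", cl$field)
    if (!colname %in% names(df))
      sdk_stop("missing_column", sprintf("table lacks column '%s'", colname))
    cells <- df[[colname]]
    if (cl$op %in% c("ge", "le", "between")) {
      vals <- suppressWarnings(as.numeric(cells))
      if (all(is.na(vals)))
        sdk_stop("non_numeric_column",
                 sprintf("column '%s' has no numeric values for op '%s'", colname, cl$op))
      if (anyNA(vals) && any(nzchar(trimws(cells)) & is.na(vals)))
        sdk_warn("non_numeric_cell",
                 sprintf("column '%s': non-numeric cells excluded from numeric clause", colname))
      ok <- switch(cl$op,
        ge = vals >= as.numeric(cl$value[1]),
        le = vals <= as.numeric(cl$value[1]),
        between = vals >= as.numeric(cl$value[1]) & vals <= as.numeric(cl$value[2]))
      ok[is.na(ok)] <- FALSE
      mask <- mask & ok
    } else if (cl$op == "matches") {
      mask <- mask & grepl(cl$value, cells)
    } else if (cl$op == "in") {
      mask <- mask & cells %in% cl$value
    } else {
      sdk_stop("invalid_filter", sprintf("op '%s' unsupported on table columns", cl$op))
    }
  }
  entry_set(unique(ids[mask]), set_name = set_name,
            db_name = basename(table_path), description = "tab_filter result")
}
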