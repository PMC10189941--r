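# PEFF 1.0 support. PEFF is FASTA with a '#'-prefixed file-header block and
# structured backslash key-value tags in each entry header encoding variants,
# modifications and sequence processing.

#' Parse PEFF header tags
#'
#' Parses the tag portion of a PEFF entry line (everything after
#' `>prefix:accession `) into a list of tags. Each tag is
#' `list(key = <string>, values = <list of character vectors>)`: scalar tags
#' such as `\PName=...` yield one single-element tuple; positional tags such
#' as `\VariantSimple=(3|A)(5|T)` yield one tuple per parenthesized group,
#' split on `|`.
#'
#' @param remainder The tag portion of a PEFF entry header line.
#' @return List of tags (possibly empty).
#' @export
#' @examples
#' parse_peff_tags("\\PName=Test protein \\Length=10 \\VariantSimple=(3|A)(5|T)")
parse_peff_tags <- function(remainder) {
  if (!is_string(remainder)) sdk_stop("malformed_tag", "tag string must be a single string")
  remainder <- trimws(remainder)
  if (!nzchar(remainder)) return(list())
  if (!startsWith(remainder, "\\"))
    sdk_stop("malformed_tag", "tag block must start with '\\'")
  pieces <- strsplit(remainder, "\\", fixed = TRUE)[[1]]
  pieces <- pieces[nzchar(trimws(pieces))]
  lapply(pieces, function(piece) {
    piece <- trimws(piece)
    eq <- regexpr("=", piece, fixed = TRUE)
    if (eq == -1L) sdk_stop("malformed_tag", paste("tag without '=':", piece))
    key <- substr(piece, 1L, eq - 1L)
    if (!nzchar(key)) sdk_stop("malformed_tag", "empty tag key")
    value <- substr(piece, eq + 1L, nchar(piece))
    if (startsWith(value, "(")) {
      list(key = key, values = .parse_tuple_groups(value, key))
    } else {
      list(key = key, values = list(value))
    }
  })
}

# "(a|b|c)(d|e)" -> list(c("a","b","c"), c("d","e"))
.parse_tuple_groups <- function(value, key) {
  groups <- list()
  i <- 1L; n <- nchar(value)
  while (i <= n) {
    ch <- substr(value, i, i)
    if (ch == " ") { i <- i + 1L; next }
    if (ch != "(")
      sdk_stop("malformed_tag", sprintf("unexpected '%s' in %s tuple list", ch, key))
    close_at <- regexpr(")", substr(value, i, n), fixed = TRUE)
    if (close_at == -1L)
      sdk_stop("malformed_tag", paste("unbalanced parenthesis in tag", key))
    inner <- substr(value, i + 1L, i + close_at - 2L)
    groups[[length(groups) + 1L]] <- strsplit(inner, "|", fixed = TRUE)[[1]]
    i <- i + close_at
  }
  if (!length(groups)) sdk_stop("malformed_tag", paste("empty tuple list in tag", key))
  groups
}

#' Format PEFF header tags
#'
#' Exact inverse of [parse_peff_tags()] on the tag model:
#' `parse_peff_tags(format_peff_tags(tags))` is the identity.
#'
#' @param tags List of tags as returned by [parse_peff_tags()].
#' @return A single tag string (no leading space), `""` for an empty list.
#' @export
format_peff_tags <- function(tags) {
  if (!length(tags)) return("")
  paste(vapply(tags, function(tag) {
    vals <- tag$values
    if (length(vals) == 1L && length(vals[[1]]) == 1L && !grepl("^\\(", vals[[1]])) {
      paste0("\\", tag$key, "=", vals[[1]])
    } else {
      paste0("\\", tag$key, "=",
             paste(vapply(vals, function(v) paste0("(", paste(v, collapse = "|"), ")"),
                          character(1)), collapse = ""))
    }
  }, character(1)), collapse = " ")
}

# --- features <-> tags -------------------------------------------------------

#' Render features as PEFF tags
#'
#' Maps the feature controlled vocabulary onto PEFF positional tags:
#' processing features (`SIGNAL`, `CHAIN`, `PROPEP`, `TRANSIT`, `INIT_MET`)
#' become `Processed` tuples `(start|end|term)`; single-residue `VARIANT`
#' becomes `VariantSimple` `(pos|residue)`; `MOD_RES` becomes `ModRes`
#' `(pos|pos|name)`. `CONFLICT` features have no PEFF rendering and are
#' dropped with a warning. [peff_tags_to_features()] is the inverse.
#'
#' @param features List of [feature()] objects.
#' @return List of PEFF tags (see [parse_peff_tags()]).
#' @export
features_to_peff_tags <- function(features) {
  processed <- list(); variants <- list(); modres <- list()
  for (f in features) {
    if (f$kind %in% names(PROCESSED_TERMS)) {
      processed[[length(processed) + 1L]] <-
        c(as.character(f$start), as.character(f$end), PROCESSED_TERMS[[f$kind]])
    } else if (f$kind == "VARIANT" && f$start == f$end && nchar(f$payload) == 1L) {
      variants[[length(variants) + 1L]] <- c(as.character(f$start), f$payload)
    } else if (f$kind == "MOD_RES") {
      modres[[length(modres) + 1L]] <-
        c(as.character(f$start), as.character(f$end), f$payload)
    } else {
      sdk_warn("unmapped_feature",
               sprintf("feature %s %d..%d has no PEFF tag rendering; dropped",
                       f$kind, f$start, f$end))
    }
  }
  tags <- list()
  if (length(processed)) tags[[length(tags) + 1L]] <- list(key = "Processed", values = processed)
  if (length(variants)) tags[[length(tags) + 1L]] <- list(key = "VariantSimple", values = variants)
  if (length(modres)) tags[[length(tags) + 1L]] <- list(key = "ModRes", values = modres)
  tags
}

#' Decode features from PEFF tags
#'
#' Inverse of [features_to_peff_tags()]: reads `Processed`, `VariantSimple`
#' and `ModRes` tags back into [feature()] objects. Unrecognized tags are
#' left untouched (the PEFF reader keeps them as entry metadata).
#'
#' @param tags List of PEFF tags.
#' @return List of [feature()] objects.
#' @export
peff_tags_to_features <- function(tags) {
  term_to_kind <- stats::setNames(names(PROCESSED_TERMS), PROCESSED_TERMS)
  feats <- list()
  for (tag in tags) {
    if (tag$key == "Processed") {
      for (v in tag$values) {
        if (length(v) < 3L) sdk_stop("malformed_tag", "Processed tuple needs (start|end|term)")
        kind <- term_to_kind[[v[3]]]
        if (is.null(kind)) {
          sdk_warn("unmapped_feature", paste("unknown Processed term:", v[3]))
          next
        }
        feats[[length(feats) + 1L]] <-
          feature(kind, as.integer(v[1]), as.integer(v[2]), source_key = "Processed")
      }
    } else if (tag$key == "VariantSimple") {
      for (v in tag$values) {
        if (length(v) < 2L) sdk_stop("malformed_tag", "VariantSimple tuple needs (pos|residue)")
        pos <- as.integer(v[1])
        feats[[length(feats) + 1L]] <-
          feature("VARIANT", pos, pos, payload = v[2], source_key = "VariantSimple")
      }
    } else if (tag$key == "ModRes") {
      for (v in tag$values) {
        if (length(v) < 3L) sdk_stop("malformed_tag", "ModRes tuple needs (start|end|name)")
        feats[[length(feats) + 1L]] <-
          feature("MOD_RES", as.integer(v[1]), as.integer(v[2]),
                  payload = v[3], source_key = "ModRes")
      }
    }
  }
  feats
}

# --- PEFF file I/O -----------------------------------------------------------

# meta keys written/read in the PEFF file-header block
.PEFF_META_KEYS <- c(db_name = "DbName", db_version = "DbVersion",
                     db_source = "DbSource", sequence_type = "SequenceType",
                     n_entries = "NumberOfEntries")

#' Read a PEFF 1.0 file
#'
#' The file must begin with a `# PEFF` magic comment; `# Key=Value` lines up
#' to the `# //` terminator populate the database metadata. Entry lines
#' `>prefix:ACC \tags...` are decoded into [protein_entry()] objects with
#' features taken from the positional tags; scalar and unrecognized tags are
#' kept in the entry's `meta` so that writing the file back preserves them.
#'
#' @param path Path to a PEFF file.
#' @return `list(meta = database_meta, entries = list of protein_entry)`.
#' @export
read_peff <- function(path) {
  if (!file.exists(path)) sdk_stop("file_unreadable", paste("no such file:", path))
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  if (!length(lines) || !grepl("^# *PEFF", lines[1]))
    sdk_stop("not_peff", paste(path, "is missing the '# PEFF' magic"))

  extra <- list()
  i <- 2L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    body <- trimws(sub("^#", "", lines[i]))
    i <- i + 1L
    if (body == "//") break
    eq <- regexpr("=", body, fixed = TRUE)
    if (eq > 0L) extra[[substr(body, 1L, eq - 1L)]] <- substr(body, eq + 1L, nchar(body))
  }

  meta <- database_meta(
    db_name = extra[["DbName"]] %||% "unnamed",
    db_version = extra[["DbVersion"]] %||% "1",
    db_source = .safe_source(extra[["DbSource"]]),
    sequence_type = if (identical(extra[["SequenceType"]], "NA")) "NA" else "AA",
    extra = extra
  )

  entries <- list()
  header <- NULL; chunks <- character(); lineno <- i - 1L
  flush <- function(header, chunks, lineno) {
    m <- regmatches(header, regexec("^>([^: ]+):(\\S+)\\s*(.*)$", header))[[1]]
    if (!length(m))
      sdk_stop("malformed_header",
               sprintf("line %d: PEFF entry header must be '>prefix:accession'", lineno))
    tags <- withCallingHandlers(
      parse_peff_tags(m[4]),
      error = function(e) {
        if (inherits(e, "seqdbkit_malformed_tag"))
          sdk_stop("malformed_tag", sprintf("line %d: %s", lineno, conditionMessage(e)))
      }
    )
    feats <- peff_tags_to_features(tags)
    entry_meta <- list(); desc <- ""
    for (tag in tags) {
      if (tag$key %in% c("Processed", "VariantSimple", "ModRes")) next
      if (length(tag$values) == 1L && length(tag$values[[1]]) == 1L) {
        entry_meta[[tag$key]] <- tag$values[[1]]
      } else {
        # unrecognized positional tag: keep its formatted text verbatim
        entry_meta[[tag$key]] <- sub("^\\\\[^=]+=", "",
                                     format_peff_tags(list(tag)))
      }
    }
    if (!is.null(entry_meta[["PName"]])) desc <- entry_meta[["PName"]]
    protein_entry(m[3], paste(chunks, collapse = ""), description = desc,
                  prefix = m[2], features = feats, meta = entry_meta)
  }
  while (i <= length(lines)) {
    line <- sub("[[:space:]]+$", "", lines[i])
    if (nzchar(line)) {
      if (startsWith(line, ">")) {
        if (!is.null(header)) entries[[length(entries) + 1L]] <- flush(header, chunks, lineno)
        header <- line; chunks <- character(); lineno <- i
      } else if (!startsWith(line, "#")) {
        if (is.null(header)) sdk_stop("not_peff", "sequence data before first entry header")
        chunks <- c(chunks, gsub("[[:space:]]", "", line))
      }
    }
    i <- i + 1L
  }
  if (!is.null(header)) entries[[length(entries) + 1L]] <- flush(header, chunks, lineno)
  meta$n_entries <- length(entries)
  list(meta = meta, entries = entries)
}

.safe_source <- function(x) {
  if (is.null(x) || !x %in% c("uniprot", "ncbi", "ensembl", "custom")) "custom" else x
}

#' Write a PEFF 1.0 file
#'
#' Emits a `# PEFF 1.0` magic line, one `# //`-terminated file-header block
#' built from the metadata, then one record per entry with its features
#' encoded as positional tags ([features_to_peff_tags()]) and its `meta`
#' key-values as scalar tags. `read_peff(write_peff(...))` preserves all
#' modeled fields.
#'
#' @param meta A [database_meta()].
#' @param entries List of [protein_entry()] objects.
#' @param path Output path.
#' @param wrap Sequence line width; `0` (default) leaves sequences unwrapped.
#' @return `path`, invisibly.
#' @export
write_peff <- function(meta, entries, path, wrap = 0L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# PEFF 1.0", con)
  hdr <- meta$extra
  hdr[["DbName"]] <- meta$db_name
  hdr[["DbVersion"]] <- meta$db_version
  hdr[["DbSource"]] <- meta$db_source
  hdr[["SequenceType"]] <- meta$sequence_type
  hdr[["NumberOfEntries"]] <- as.character(length(entries))
  for (key in names(hdr)) writeLines(paste0("# ", key, "=", hdr[[key]]), con)
  writeLines("# //", con)
  for (e in entries) {
    tags <- features_to_peff_tags(e$features)
    scalar <- lapply(names(e$meta), function(k) {
      v <- e$meta[[k]]
      if (startsWith(v, "(")) list(key = k, values = .parse_tuple_groups(v, k))
      else list(key = k, values = list(v))
    })
    if (nzchar(e$description) && is.null(e$meta[["PName"]]))
      scalar <- c(list(list(key = "PName", values = list(e$description))), scalar)
    line <- paste0(">", e$prefix, ":", e$accession)
    tagstr <- format_peff_tags(c(scalar, tags))
    if (nzchar(tagstr)) line <- paste(line, tagstr)
    writeLines(line, con)
    writeLines(wrap_sequence(e$sequence, wrap), con)
  }
  invisible(path)
}
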