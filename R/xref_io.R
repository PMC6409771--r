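#' File dialect for metabolite cross-reference tables
#'
#' Describes the MetaNetX `chem_xref.tsv` layout: a tab-separated file whose
#' data rows carry four columns in order — the source identifier with a
#' database prefix (`bigg:10fthf`), the MNXRef identifier, an evidence tag,
#' and a description holding one or more names separated by `|`. Lines
#' starting with the comment prefix are headers/comments.
#'
#' @param comment_prefix Single character marking comment/header lines.
#' @param column_separator Column separator (tab in the standard files).
#' @param name_separator Character splitting multiple names inside the
#'   description column.
#' @param prefix_separator Character separating the database prefix from the
#'   local identifier in the first column.
#' @return A list of class `xref_dialect`.
#' @examples
#' d <- xref_dialect()
#' parse_xref("bigg:10fthf\tMNXM237\tidentity\t10-Formyltetrahydrofolate", d)
#' @export
xref_dialect <- function(comment_prefix = "#", column_separator = "\t",
                         name_separator = "|", prefix_separator = ":") {
  for (f in c(comment_prefix, column_separator, name_separator, prefix_separator)) {
    if (!is.character(f) || length(f) != 1L || !nzchar(f)) {
      stop_config("all dialect fields must be non-empty single strings")
    }
  }
  if (identical(name_separator, column_separator)) {
    stop_config("name_separator must differ from column_separator")
  }
  structure(
    list(comment_prefix = comment_prefix, column_separator = column_separator,
         name_separator = name_separator, prefix_separator = prefix_separator),
    class = "xref_dialect"
  )
}

#' Preprocessing filter configuration
#'
#' The standard preprocessing applied before any audit: duplicate BiGG
#' entries whose local identifier starts with `M_` are dropped (they shadow
#' the real BiGG identifier), records naming the artificial growth compound
#' `biomass` are dropped (case-insensitive whole-name match, so real
#' compounds merely containing the substring survive), and rows whose source
#' database is the MetaNetX namespace itself are dropped so that only the
#' external databases are audited.
#'
#' @param drop_local_id_prefixes Named list: database prefix -> character
#'   vector of local-identifier prefixes whose records are removed. Set
#'   `list(bigg = "M")` to reproduce the literal-`M` variant.
#' @param drop_names Names whose case-insensitive exact match removes a
#'   record.
#' @param drop_self_references Drop records whose database prefix is one of
#'   `metanetx_prefixes`.
#' @param metanetx_prefixes Prefix tokens treated as the MetaNetX namespace.
#' @return A list of class `xref_filter_config`.
#' @export
filter_config <- function(drop_local_id_prefixes = list(bigg = "M_"),
                          drop_names = "biomass",
                          drop_self_references = TRUE,
                          metanetx_prefixes = c("mnx", "MNX", "metanetx")) {
  if (!is.list(drop_local_id_prefixes) ||
      (length(drop_local_id_prefixes) > 0L && is.null(names(drop_local_id_prefixes)))) {
    stop_config("drop_local_id_prefixes must be a named list")
  }
  ok <- vapply(drop_local_id_prefixes, function(p) is.character(p) && all(nzchar(p)), TRUE)
  if (!all(ok) || any(!nzchar(names(drop_local_id_prefixes)))) {
    stop_config("drop_local_id_prefixes entries must be non-empty strings")
  }
  if (!is.character(drop_names) || any(!nzchar(drop_names))) {
    stop_config("drop_names must be non-empty strings")
  }
  structure(
    list(drop_local_id_prefixes = drop_local_id_prefixes,
         drop_names = drop_names,
         drop_self_references = isTRUE(drop_self_references),
         metanetx_prefixes = metanetx_prefixes),
    class = "xref_filter_config"
  )
}

new_xref_records <- function(source_db, source_id, mnx_id, evidence, names) {
  out <- data.frame(source_db = as.character(source_db),
                    source_id = as.character(source_id),
                    mnx_id = as.character(mnx_id),
                    evidence = as.character(evidence),
                    stringsAsFactors = FALSE)
  out$names <- names
  class(out) <- c("xref_records", "data.frame")
  out
}

# Trim, drop empties, deduplicate keeping first occurrence.
clean_names <- function(nm) {
  nm <- trimws(nm)
  nm <- nm[nzchar(nm)]
  nm[!duplicated(nm)]
}

#' Construct cross-reference records in memory
#'
#' @param source_db,source_id,mnx_id,evidence Character vectors, recycled to
#'   a common length.
#' @param names List of character vectors (one per record) or a single
#'   character vector when every record has one name. Names are trimmed,
#'   empties dropped and within-record duplicates removed (first kept).
#' @return An `xref_records` data frame with a list column `names`.
#' @export
xref_records <- function(source_db, source_id, mnx_id, evidence = "", names = list()) {
  n <- max(length(source_db), length(source_id), length(mnx_id))
  if (any(!nzchar(source_db)) || any(!nzchar(source_id))) {
    stop_config("source_db and source_id must be non-empty")
  }
  if (is.character(names)) names <- as.list(names)
  if (length(names) == 0L) names <- rep(list(character(0)), n)
  names <- lapply(names, clean_names)
  new_xref_records(rep_len(source_db, n), rep_len(source_id, n),
                   rep_len(mnx_id, n), rep_len(evidence, n), names)
}

#' Parse a cross-reference table
#'
#' Splits every non-comment line on the column separator; the first column is
#' split at the *first* prefix separator into database prefix and local
#' identifier, and the fourth (description) column is split into names.
#' Records are returned in input order and no cross-record deduplication is
#' performed. Lines whose first column carries no prefix separator are
#' skipped with a warning and counted in the attached parse report.
#'
#' @param lines Character vector of raw lines.
#' @param dialect An [xref_dialect()].
#' @return An `xref_records` data frame; attribute `parse_report` holds
#'   counts of lines seen, comments, blanks, records kept and records
#'   skipped for lacking a database prefix.
#' @export
parse_xref <- function(lines, dialect = xref_dialect()) {
  if (!is.character(lines)) stop_usage("parse_xref() expects a character vector of lines")
  n_total <- length(lines)
  is_comment <- startsWith(lines, dialect$comment_prefix)
  is_blank <- !nzchar(trimws(lines))
  keep <- !is_comment & !is_blank
  lineno <- which(keep)
  body <- lines[keep]

  parts <- strsplit(body, dialect$column_separator, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    bad <- which(nf < 2L)[1L]
    stop_parse(sprintf("line %d: expected at least 2 columns separated by %s, found %d",
                       lineno[bad], deparse(dialect$column_separator), nf[bad]),
               line = lineno[bad])
  }
  col1 <- vapply(parts, `[[`, "", 1L)
  mnx <- vapply(parts, `[[`, "", 2L)
  evidence <- vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else "", "")
  descr <- vapply(parts, function(p) if (length(p) >= 4L) p[[4L]] else "", "")

  sep_at <- regexpr(dialect$prefix_separator, col1, fixed = TRUE)
  no_prefix <- as.integer(sep_at) < 0L
  if (any(no_prefix)) {
    warning(sprintf("skipped %d record(s) whose first column has no %s prefix separator (first at line %d)",
                    sum(no_prefix), deparse(dialect$prefix_separator),
                    lineno[which(no_prefix)[1L]]))
  }
  ok <- !no_prefix
  col1 <- col1[ok]; sep_at <- as.integer(sep_at)[ok]
  source_db <- substr(col1, 1L, sep_at - 1L)
  source_id <- substr(col1, sep_at + nchar(dialect$prefix_separator), nchar(col1))
  bad_id <- !nzchar(source_db) | !nzchar(source_id)
  if (any(bad_id)) {
    stop_parse(sprintf("line %d: empty database prefix or local identifier",
                       lineno[ok][which(bad_id)[1L]]))
  }
  names_list <- lapply(strsplit(descr[ok], dialect$name_separator, fixed = TRUE),
                       clean_names)
  out <- new_xref_records(source_db, source_id, mnx[ok], evidence[ok], names_list)
  attr(out, "parse_report") <- list(
    n_lines = n_total, n_comments = sum(is_comment), n_blank = sum(is_blank & !is_comment),
    n_records = nrow(out), n_skipped_no_prefix = sum(no_prefix))
  out
}

#' Read a cross-reference file
#'
#' @param path Path to a chem_xref-dialect TSV file.
#' @inheritParams parse_xref
#' @return See [parse_xref()].
#' @export
read_xref <- function(path, dialect = xref_dialect()) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_usage(sprintf("input file not found: %s", path))
  }
  parse_xref(readLines(path, warn = FALSE), dialect)
}

#' Write records as a cross-reference table
#'
#' Emits one header comment line and one line per record such that
#' [parse_xref()] reproduces the records field for field. Values containing
#' the column or name separator cannot be represented and raise a
#' serialization error.
#'
#' @param records An `xref_records` data frame.
#' @param path Output file path, or `NULL` to return the lines invisibly
#'   without writing.
#' @inheritParams parse_xref
#' @return Invisibly, the character vector of emitted lines.
#' @export
write_xref <- function(records, path = NULL, dialect = xref_dialect()) {
  records <- as_xref_records(records)
  all_names <- unlist(records$names, use.names = FALSE)
  forbidden <- function(x, what) {
    hit <- grepl(dialect$name_separator, x, fixed = TRUE) |
      grepl(dialect$column_separator, x, fixed = TRUE)
    if (any(hit)) {
      stop_serialize(sprintf("%s %s contains a reserved separator and cannot be serialized",
                             what, deparse(x[hit][1L])))
    }
  }
  forbidden(all_names, "name")
  for (col in c("source_db", "source_id", "mnx_id", "evidence")) {
    bad <- grepl(dialect$column_separator, records[[col]], fixed = TRUE)
    if (any(bad)) stop_serialize(sprintf("%s %s contains the column separator",
                                         col, deparse(records[[col]][bad][1L])))
  }
  header <- paste0(dialect$comment_prefix,
                   paste(c("source", "mnx_id", "evidence", "description"),
                         collapse = dialect$column_separator))
  descr <- vapply(records$names, paste, "", collapse = dialect$name_separator)
  body <- paste(paste0(records$source_db, dialect$prefix_separator, records$source_id),
                records$mnx_id, records$evidence, descr,
                sep = dialect$column_separator)
  lines <- c(header, if (nrow(records) > 0L) body)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

as_xref_records <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("source_db", "source_id", "mnx_id", "evidence", "names") %in% names(records))) {
    stop_usage("expected an xref_records data frame (see xref_records())")
  }
  records
}

#' Apply preprocessing filters
#'
#' Rules are evaluated in order for each record — (a) configured local-ID
#' prefix for the record's database, (b) case-insensitive match of any name
#' against `drop_names`, (c) source database is the MetaNetX namespace — and
#' the first matching rule takes the blame in the report. Surviving records
#' are unmodified and keep their input order; applying the same
#' configuration twice is a no-op.
#'
#' @param records An `xref_records` data frame.
#' @param config A [filter_config()].
#' @return A list with elements `records` (the survivors) and `report`, a
#'   `xref_filter_report` holding `records_in`, `records_out` and the
#'   per-rule drop counts (their sum always reconciles with the totals).
#' @export
apply_filters <- function(records, config = filter_config()) {
  records <- as_xref_records(records)
  n <- nrow(records)
  match_a <- logical(n)
  for (db in names(config$drop_local_id_prefixes)) {
    pref <- config$drop_local_id_prefixes[[db]]
    in_db <- records$source_db == db
    if (any(in_db)) {
      hit <- rep(FALSE, sum(in_db))
      for (p in pref) hit <- hit | startsWith(records$source_id[in_db], p)
      match_a[in_db] <- hit
    }
  }
  low_drop <- tolower(config$drop_names)
  match_b <- vapply(records$names, function(nm) any(tolower(nm) %in% low_drop), TRUE)
  match_c <- if (config$drop_self_references) {
    records$source_db %in% config$metanetx_prefixes
  } else rep(FALSE, n)

  by_a <- match_a
  by_b <- !by_a & match_b
  by_c <- !by_a & !by_b & match_c
  keep <- !(by_a | by_b | by_c)
  report <- structure(
    list(records_in = n, records_out = sum(keep),
         dropped_by_rule = c(local_id_prefix = sum(by_a),
                             drop_name = sum(by_b),
                             self_reference = sum(by_c))),
    class = "xref_filter_report")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(records)
  list(records = out, report = report)
}

#' @export
print.xref_filter_report <- function(x, ...) {
  cat(sprintf("cross-reference filter report: %d in, %d out\n",
              x$records_in, x$records_out))
  for (r in names(x$dropped_by_rule)) {
    cat(sprintf("  dropped by %-16s %d\n", r, x$dropped_by_rule[[r]]))
  }
  invisible(x)
}
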