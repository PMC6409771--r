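# Report writers tying the pipeline together: parse -> filter -> index ->
# audit -> TSV/JSON files. These are the programmatic equivalents of a
# command-line surface; the numbered scripts under analysis/ drive them.

resolve_input <- function(input, dialect) {
  if (is.character(input)) {
    records <- read_xref(input, dialect)
  } else {
    records <- as_xref_records(input)
  }
  records
}

prepare_collection <- function(input, dialect, filters, quiet) {
  records <- resolve_input(input, dialect)
  filtered <- apply_filters(records, filters)
  if (!quiet) {
    message(sprintf("parsed %d record(s); filters kept %d (dropped: %s)",
                    filtered$report$records_in, filtered$report$records_out,
                    paste(sprintf("%s=%d", names(filtered$report$dropped_by_rule),
                                  filtered$report$dropped_by_rule), collapse = ", ")))
  }
  if (nrow(filtered$records) == 0L) {
    stop_empty("no records left after filtering; nothing to audit")
  }
  collection <- build_indexes(filtered$records)
  if (!quiet) {
    for (idx in collection$indexes) {
      message(sprintf("indexed %s: %d IDs, %d names, %d links",
                      idx$db_label, idx$n_ids, idx$n_names, idx$n_links))
    }
  }
  list(collection = collection, filter_report = filtered$report)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], round, 2L) # percentages/means to 2 decimals
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

stats_to_row <- function(x) as.data.frame(unclass(x), stringsAsFactors = FALSE)

#' Run the intra-database audit and write its reports
#'
#' Writes four TSV tables (name ambiguity, identifier multiplicity, top-k
#' rankings, MNXRef-link multiplicity — one row or block per database) plus
#' a JSON bundle of all statistics at full precision.
#'
#' @param input Path to a chem_xref-dialect file, or an `xref_records` data
#'   frame.
#' @param output_dir Directory for the report files (created if needed).
#' @param dialect An [xref_dialect()].
#' @param filters A [filter_config()].
#' @param top_k Entries per database in the ranking table.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a named character vector of the files written.
#' @export
run_audit_intra <- function(input, output_dir, dialect = xref_dialect(),
                            filters = filter_config(), top_k = 10L,
                            quiet = FALSE) {
  prep <- prepare_collection(input, dialect, filters, quiet)
  coll <- prep$collection
  dbs <- names(coll$indexes)
  amb <- do.call(rbind, lapply(dbs, function(d) stats_to_row(name_ambiguity(coll$indexes[[d]]))))
  mult <- do.call(rbind, lapply(dbs, function(d) stats_to_row(id_multiplicity(coll$indexes[[d]]))))
  mnx <- do.call(rbind, lapply(dbs, function(d) {
    tryCatch(stats_to_row(mnx_link_stats(coll, d)),
             xref_empty_namespace_error = function(e) NULL)
  }))
  tops <- do.call(rbind, lapply(dbs, function(d) {
    rbind(cbind(db_label = d, mode = "ambiguous-names",
                top_entries(coll$indexes[[d]], "ambiguous-names", top_k)),
          cbind(db_label = d, mode = "multi-ids",
                top_entries(coll$indexes[[d]], "multi-ids", top_k)))
  }))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    ambiguity = write_tsv(amb, file.path(output_dir, "name_ambiguity.tsv")),
    multiplicity = write_tsv(mult, file.path(output_dir, "id_multiplicity.tsv")),
    top_entries = write_tsv(tops, file.path(output_dir, "top_entries.tsv")),
    mnx_links = write_tsv(mnx, file.path(output_dir, "mnx_link_multiplicity.tsv")))
  bundle <- list(filter_report = unclass(prep$filter_report),
                 ambiguity = amb, multiplicity = mult, mnx_links = mnx,
                 top_entries = tops)
  json_path <- file.path(output_dir, "intra_audit.json")
  jsonlite::write_json(bundle, json_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, bundle = json_path)
  invisible(files)
}

# Wide matrix (rows = target databases, columns = source databases) from the
# long pairwise summary, mirroring the usual presentation of mapping tables.
pairwise_matrix <- function(summary, value) {
  dbs <- sort_c(unique(c(summary$source_db, summary$target_db)))
  m <- matrix(NA_real_, length(dbs), length(dbs), dimnames = list(dbs, dbs))
  for (i in seq_len(nrow(summary))) {
    m[summary$target_db[i], summary$source_db[i]] <- summary[[value]][i]
  }
  df <- data.frame(Database = dbs, round(m, 2L), check.names = FALSE,
                   stringsAsFactors = FALSE)
  df
}

#' Run the inter-database mapping audit and write its reports
#'
#' For each requested method writes two TSV matrices — mapped counts and
#' percentage of mapped identifiers hitting more than one target — with
#' source databases as columns and target databases as rows, plus a JSON
#' file with the full per-pair detail.
#'
#' @inheritParams run_audit_intra
#' @param method Mapping bridge(s): `"name"`, `"mnx"`, or both (default).
#' @return Invisibly, a named character vector of the files written.
#' @export
run_audit_inter <- function(input, output_dir, method = c("name", "mnx"),
                            dialect = xref_dialect(), filters = filter_config(),
                            quiet = FALSE) {
  if (!all(method %in% c("name", "mnx")) || length(method) < 1L) {
    stop_usage("method must be a subset of c(\"name\", \"mnx\")")
  }
  prep <- prepare_collection(input, dialect, filters, quiet)
  coll <- prep$collection
  if (length(coll$indexes) < 2L) {
    stop_config("inter-database audit needs at least 2 databases in the input")
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  detail <- list()
  for (m in unique(method)) {
    summ <- pairwise_summary(coll, m)
    detail[[m]] <- summ
    files <- c(files, stats::setNames(
      c(write_tsv(pairwise_matrix(summ, "n_mapped"),
                  file.path(output_dir, sprintf("mapped_counts_%s.tsv", m))),
        write_tsv(pairwise_matrix(summ, "pct_nonunique_of_mapped"),
                  file.path(output_dir, sprintf("nonunique_pct_%s.tsv", m)))),
      paste0(c("counts_", "nonunique_"), m)))
  }
  json_path <- file.path(output_dir, "inter_audit.json")
  jsonlite::write_json(detail, json_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, bundle = json_path)
  invisible(files)
}

#' Detect inconsistencies and write the findings report
#'
#' Runs the three detectors — ambiguous names within each database,
#' cross-database name conflicts over all database pairs, and synonym
#' chains within each database — and writes the combined findings.
#'
#' @inheritParams run_audit_intra
#' @param kinds Which finding kinds to include.
#' @param formats Output formats to write (`"tsv"`, `"json"`, or both).
#' @param max_path_length Witness-chain truncation for [synonym_chains()].
#' @return Invisibly, a list with `findings` and the files written.
#' @export
run_conflicts <- function(input, output_dir,
                          kinds = c("intra_ambiguous", "cross_db_conflict", "synonym_chain"),
                          formats = c("tsv", "json"), max_path_length = 11L,
                          dialect = xref_dialect(), filters = filter_config(),
                          quiet = FALSE) {
  allowed <- c("intra_ambiguous", "cross_db_conflict", "synonym_chain")
  if (!all(kinds %in% allowed)) stop_usage("unknown finding kind requested")
  if (!all(formats %in% c("tsv", "json"))) stop_usage("formats must be tsv and/or json")
  prep <- prepare_collection(input, dialect, filters, quiet)
  coll <- prep$collection
  dbs <- names(coll$indexes)
  findings <- list()
  if ("intra_ambiguous" %in% kinds) {
    for (d in dbs) {
      findings <- c(findings, intra_ambiguous_findings(coll$indexes[[d]], coll))
    }
  }
  if ("cross_db_conflict" %in% kinds && length(dbs) >= 2L) {
    for (i in seq_along(dbs)) {
      for (j in seq_along(dbs)) {
        if (j <= i) next
        findings <- c(findings, cross_db_conflicts(coll, dbs[i], dbs[j]))
      }
    }
  }
  if ("synonym_chain" %in% kinds) {
    for (d in dbs) {
      findings <- c(findings, synonym_chains(coll$indexes[[d]], max_path_length))
    }
  }
  findings <- sort_findings(findings)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  if ("tsv" %in% formats) {
    p <- file.path(output_dir, "findings.tsv")
    writeLines(render_findings(findings, "tsv"), p)
    files <- c(files, tsv = p)
  }
  if ("json" %in% formats) {
    p <- file.path(output_dir, "findings.json")
    writeLines(render_findings(findings, "json"), p)
    files <- c(files, json = p)
  }
  if (!quiet) message(sprintf("detected %d finding(s)", length(findings)))
  invisible(list(findings = findings, files = files))
}

#' Generate a synthetic snapshot and write it with its ground truth
#'
#' @param config A [synthetic_config()].
#' @param output_dir Directory for `chem_xref_synthetic.tsv` and
#'   `ground_truth.json`.
#' @param dialect An [xref_dialect()] for the emitted table.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the list returned by [generate_xref()] with the file
#'   paths attached.
#' @export
run_simulate <- function(config = synthetic_config(), output_dir,
                         dialect = xref_dialect(), quiet = FALSE) {
  gen <- generate_xref(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(output_dir, "chem_xref_synthetic.tsv")
  write_xref(gen$records, tsv, dialect)
  truth_path <- file.path(output_dir, "ground_truth.json")
  jsonlite::write_json(gen$truth, truth_path, auto_unbox = TRUE, digits = NA)
  if (!quiet) {
    message(sprintf("wrote %d synthetic record(s) across %d database(s)",
                    nrow(gen$records), gen$config$n_databases))
  }
  gen$files <- c(records = tsv, truth = truth_path)
  invisible(gen)
}
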