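# Long-format link tables underlying every index and every brute-force
# recount: one row per distinct (db, id, name) or (db, id, mnx) association.
name_link_table <- function(records) {
  k <- lengths(records$names)
  out <- data.frame(db = rep(records$source_db, k),
                    id = rep(records$source_id, k),
                    name = unlist(records$names, use.names = FALSE),
                    stringsAsFactors = FALSE)
  out[!duplicated(out), , drop = FALSE]
}

mnx_link_table <- function(records) {
  out <- data.frame(db = records$source_db, id = records$source_id,
                    mnx = records$mnx_id, stringsAsFactors = FALSE)
  out <- out[nzchar(out$mnx), , drop = FALSE]
  out[!duplicated(out), , drop = FALSE]
}

# Named list mapping each level of `keys` (restricted to `all_keys`) to the
# sorted unique values attached to it; keys without values get character(0).
assoc <- function(keys, values, all_keys) {
  all_keys <- sort_c(unique(all_keys))
  out <- rep(list(character(0)), length(all_keys))
  names(out) <- all_keys
  if (length(keys) > 0L) {
    sp <- split(values, keys)
    sp <- lapply(sp, function(v) sort_c(unique(v)))
    out[names(sp)] <- sp
  }
  out
}

#' Build per-database namespace indexes
#'
#' Turns filtered cross-reference records into, for every database prefix,
#' a bidirectional association structure: local ID to its set of names,
#' name to its set of local IDs (the exact transpose), and local ID to the
#' MNXRef identifiers it appears with. Duplicate links collapse; identifiers
#' that carry no name are retained (with an empty name set) and counted.
#'
#' @param records An `xref_records` data frame, normally after
#'   [apply_filters()].
#' @return A `namespace_collection`: a list with `indexes` (one
#'   `namespace_index` per database, keyed and sorted by prefix) and
#'   `mnx_links`, the distinct (db, id, mnx) table used for MNXRef-bridge
#'   queries.
#' @export
build_indexes <- function(records) {
  records <- as_xref_records(records)
  nl <- name_link_table(records)
  ml <- mnx_link_table(records)
  dbs <- sort_c(unique(records$source_db))
  indexes <- lapply(dbs, function(db) {
    ids <- records$source_id[records$source_db == db]
    nld <- nl[nl$db == db, , drop = FALSE]
    mld <- ml[ml$db == db, , drop = FALSE]
    id_to_names <- assoc(nld$id, nld$name, ids)
    name_to_ids <- assoc(nld$name, nld$id, nld$name)
    id_to_mnx <- assoc(mld$id, mld$mnx, ids)
    structure(
      list(db_label = db,
           id_to_names = id_to_names,
           name_to_ids = name_to_ids,
           id_to_mnx = id_to_mnx,
           n_ids = length(id_to_names),
           n_names = length(name_to_ids),
           n_links = nrow(nld)),
      class = "namespace_index")
  })
  names(indexes) <- dbs
  structure(list(indexes = indexes, mnx_links = ml),
            class = "namespace_collection")
}

get_index <- function(collection, db_label) {
  if (inherits(collection, "namespace_index")) return(collection)
  if (!inherits(collection, "namespace_collection")) {
    stop_usage("expected a namespace_collection (see build_indexes())")
  }
  idx <- collection$indexes[[db_label]]
  if (is.null(idx)) {
    stop_lookup(sprintf("unknown database label %s (known: %s)",
                        deparse(db_label),
                        paste(names(collection$indexes), collapse = ", ")),
                db_label = db_label)
  }
  idx
}

#' Local identifiers linked to a name
#'
#' Matching is byte-exact: case-sensitive, no whitespace or punctuation
#' normalization. An absent name yields an empty set.
#'
#' @param collection A `namespace_collection` from [build_indexes()].
#' @param db_label Database prefix to query.
#' @param name Compound name.
#' @return Sorted character vector of local identifiers.
#' @export
ids_for_name <- function(collection, db_label, name) {
  idx <- get_index(collection, db_label)
  idx$name_to_ids[[name]] %||% character(0)
}

#' MNXRef identifiers linked to a local identifier
#'
#' @inheritParams ids_for_name
#' @param local_id Local identifier within the database.
#' @return Sorted character vector of MNXRef identifiers (empty when the
#'   identifier is unknown or unlinked).
#' @export
mnx_for_id <- function(collection, db_label, local_id) {
  idx <- get_index(collection, db_label)
  idx$id_to_mnx[[local_id]] %||% character(0)
}

# Restriction of the MNXRef->local-ID transpose to one database.
mnx_to_ids_for_db <- function(collection, db_label) {
  get_index(collection, db_label) # validates the label
  ml <- collection$mnx_links
  mld <- ml[ml$db == db_label, , drop = FALSE]
  assoc(mld$mnx, mld$id, mld$mnx)
}

#' @export
print.namespace_index <- function(x, ...) {
  cat(sprintf("namespace index for %s: %d IDs, %d names, %d name links\n",
              x$db_label, x$n_ids, x$n_names, x$n_links))
  invisible(x)
}

#' @export
print.namespace_collection <- function(x, ...) {
  cat(sprintf("namespace collection: %d database(s)\n", length(x$indexes)))
  for (idx in x$indexes) {
    cat(sprintf("  %-12s %6d IDs %7d names %7d links\n",
                idx$db_label, idx$n_ids, idx$n_names, idx$n_links))
  }
  invisible(x)
}
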