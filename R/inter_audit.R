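# Shared machinery: join the source and target long link tables on the
# bridging key (a name or a MNXRef identifier) and fold the resulting ID
# pairs into a per-source-ID association covering every source identifier.
map_via_key <- function(collection, source_db, target_db, method) {
  src <- get_index(collection, source_db)
  tgt <- get_index(collection, target_db)
  if (method == "name") {
    a <- data.frame(id = rep(names(src$id_to_names), lengths(src$id_to_names)),
                    key = unlist(src$id_to_names, use.names = FALSE),
                    stringsAsFactors = FALSE)
    b <- data.frame(id = rep(names(tgt$id_to_names), lengths(tgt$id_to_names)),
                    key = unlist(tgt$id_to_names, use.names = FALSE),
                    stringsAsFactors = FALSE)
  } else {
    a <- data.frame(id = rep(names(src$id_to_mnx), lengths(src$id_to_mnx)),
                    key = unlist(src$id_to_mnx, use.names = FALSE),
                    stringsAsFactors = FALSE)
    b <- data.frame(id = rep(names(tgt$id_to_mnx), lengths(tgt$id_to_mnx)),
                    key = unlist(tgt$id_to_mnx, use.names = FALSE),
                    stringsAsFactors = FALSE)
  }
  pairs <- merge(a, b, by = "key", suffixes = c("_s", "_t"))
  entries <- assoc(pairs$id_s, pairs$id_t, names(src$id_to_names))
  structure(list(source_db = source_db, target_db = target_db,
                 method = method, entries = entries),
            class = "id_mapping")
}

#' Map identifiers between two databases via shared names
#'
#' A source identifier maps to every target identifier with which it shares
#' at least one byte-identical name (the union over all of the source
#' identifier's names). No string normalization is applied and ambiguous
#' names are treated like any other name.
#'
#' @param collection A `namespace_collection` from [build_indexes()].
#' @param source_db,target_db Database prefixes (self-mapping is allowed and
#'   useful for diagnostics).
#' @return An `id_mapping`: `entries` associates every source identifier
#'   with its (possibly empty) sorted set of target identifiers.
#' @export
map_by_name <- function(collection, source_db, target_db) {
  map_via_key(collection, source_db, target_db, "name")
}

#' Map identifiers between two databases via MNXRef identifiers
#'
#' A source identifier maps to every target identifier linked to one of its
#' MNXRef identifiers, i.e. MNXRef is used as the bridging namespace.
#'
#' @inheritParams map_by_name
#' @return An `id_mapping`; see [map_by_name()].
#' @export
map_by_mnx <- function(collection, source_db, target_db) {
  map_via_key(collection, source_db, target_db, "mnx")
}

#' Summary counts for one identifier mapping
#'
#' @param mapping An `id_mapping` from [map_by_name()] or [map_by_mnx()].
#' @return One-row data frame: `source_db`, `target_db`, `method`,
#'   `n_source_ids`, `n_mapped` (source identifiers with at least one
#'   target), `pct_mapped` (of all source identifiers), `n_nonunique`
#'   (mapped source identifiers with two or more targets) and
#'   `pct_nonunique_of_mapped` (of the mapped identifiers; 0 when nothing
#'   maps).
#' @export
mapping_stats <- function(mapping) {
  if (!inherits(mapping, "id_mapping")) stop_usage("expected an id_mapping")
  sizes <- lengths(mapping$entries)
  n_src <- length(sizes)
  n_mapped <- sum(sizes >= 1L)
  n_nonunique <- sum(sizes >= 2L)
  data.frame(source_db = mapping$source_db, target_db = mapping$target_db,
             method = mapping$method,
             n_source_ids = n_src, n_mapped = n_mapped,
             pct_mapped = if (n_src > 0L) 100 * n_mapped / n_src else 0,
             n_nonunique = n_nonunique,
             pct_nonunique_of_mapped = if (n_mapped > 0L) 100 * n_nonunique / n_mapped else 0,
             stringsAsFactors = FALSE)
}

#' Pairwise mapping summary over all database pairs
#'
#' Computes [mapping_stats()] for every ordered pair of distinct databases
#' in the collection. The resulting matrix is intentionally not symmetric:
#' databases differ in coverage and in name multiplicity, so A to B and B to
#' A mapped fractions generally differ, even though the underlying set of
#' mapped identifier *pairs* is the same in both directions.
#'
#' @inheritParams map_by_name
#' @param method `"name"` or `"mnx"`.
#' @param include_self Also include the diagnostic self-mappings (db to
#'   itself). Default off, matching the usual presentation.
#' @return Data frame with one row per ordered pair, columns as in
#'   [mapping_stats()].
#' @export
pairwise_summary <- function(collection, method = c("name", "mnx"),
                             include_self = FALSE) {
  method <- match.arg(method)
  if (!inherits(collection, "namespace_collection")) {
    stop_usage("expected a namespace_collection (see build_indexes())")
  }
  dbs <- names(collection$indexes)
  if (length(dbs) < 2L) {
    stop_config("pairwise mapping needs at least 2 databases")
  }
  rows <- list()
  for (s in dbs) {
    for (t in dbs) {
      if (!include_self && identical(s, t)) next
      rows[[length(rows) + 1L]] <- mapping_stats(map_via_key(collection, s, t, method))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.id_mapping <- function(x, ...) {
  sizes <- lengths(x$entries)
  cat(sprintf("%s -> %s via %s: %d/%d source IDs mapped, %d non-uniquely\n",
              x$source_db, x$target_db, x$method,
              sum(sizes >= 1L), length(sizes), sum(sizes >= 2L)))
  invisible(x)
}
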