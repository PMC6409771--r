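#' Name-ambiguity statistics for one database
#'
#' A name is ambiguous when it links to two or more local identifiers in the
#' same database. Reports the distinct-name count, the mean and standard
#' deviation of identifiers per name, and the count, percentage and maximum
#' of ambiguous names.
#'
#' @param index A `namespace_index` (one element of
#'   `build_indexes(...)$indexes`).
#' @param sd_type `"population"` (divisor N, the default; exact on small
#'   fixtures) or `"sample"` (divisor N-1). At database scale the two are
#'   indistinguishable.
#' @return A list of class `ambiguity_stats` with fields `db_label`,
#'   `n_names`, `mean_ids_per_name`, `sd_ids_per_name`, `n_ambiguous`,
#'   `pct_ambiguous`, `max_ids_per_name`.
#' @export
name_ambiguity <- function(index, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (!inherits(index, "namespace_index")) stop_usage("expected a namespace_index")
  if (index$n_names == 0L) {
    stop_empty(sprintf("database %s has no names to audit", index$db_label))
  }
  deg <- lengths(index$name_to_ids)
  structure(
    list(db_label = index$db_label,
         n_names = length(deg),
         mean_ids_per_name = mean(deg),
         sd_ids_per_name = spread_sd(deg, sd_type),
         n_ambiguous = sum(deg >= 2L),
         pct_ambiguous = 100 * sum(deg >= 2L) / length(deg),
         max_ids_per_name = max(deg)),
    class = "ambiguity_stats")
}

#' Identifier-multiplicity statistics for one database
#'
#' The multiplicity of an identifier is the number of names (synonyms)
#' linked to it. Mean, standard deviation and percentages are taken over
#' identifiers that carry at least one name; identifiers without any name
#' are counted separately in `n_unnamed`.
#'
#' @inheritParams name_ambiguity
#' @return A list of class `multiplicity_stats` with fields `db_label`,
#'   `n_ids`, `n_named_ids`, `mean_names_per_id`, `sd_names_per_id`,
#'   `n_multi`, `pct_multi`, `max_multiplicity`, `n_unnamed`.
#' @export
id_multiplicity <- function(index, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (!inherits(index, "namespace_index")) stop_usage("expected a namespace_index")
  if (index$n_ids == 0L) {
    stop_empty(sprintf("database %s has no identifiers to audit", index$db_label))
  }
  deg <- lengths(index$id_to_names)
  named <- deg[deg > 0L]
  n_named <- length(named)
  structure(
    list(db_label = index$db_label,
         n_ids = length(deg),
         n_named_ids = n_named,
         mean_names_per_id = if (n_named > 0L) mean(named) else NA_real_,
         sd_names_per_id = if (n_named > 0L) spread_sd(named, sd_type) else NA_real_,
         n_multi = sum(named >= 2L),
         pct_multi = if (n_named > 0L) 100 * sum(named >= 2L) / n_named else 0,
         max_multiplicity = if (n_named > 0L) max(named) else 0L,
         n_unnamed = sum(deg == 0L)),
    class = "multiplicity_stats")
}

#' MNXRef-link multiplicity statistics for one database
#'
#' One MNXRef identifier can be linked to several local identifiers within a
#' database (a deliberate merge of synonymous entries, or an error source
#' when the merged identifiers carry ambiguous names). Reports the number of
#' distinct MNXRef identifiers linking into the database, the distribution
#' of local identifiers per MNXRef identifier, and the shares of multiplied
#' links on both sides: `pct_ids_multi` is the percentage of *local*
#' identifiers that share their MNXRef identifier with another local
#' identifier, `pct_mnx_multi` the percentage of MNXRef identifiers linked
#' to two or more local identifiers.
#'
#' @param collection A `namespace_collection` from [build_indexes()].
#' @param db_label Database prefix.
#' @inheritParams name_ambiguity
#' @return A list of class `mnx_link_stats` with fields `db_label`, `n_ids`,
#'   `n_mnx`, `mean_ids_per_mnx`, `sd_ids_per_mnx`, `n_mnx_multi`,
#'   `pct_ids_multi`, `pct_mnx_multi`, `max_ids_per_mnx`.
#' @export
mnx_link_stats <- function(collection, db_label, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  idx <- get_index(collection, db_label)
  m2i <- mnx_to_ids_for_db(collection, db_label)
  if (length(m2i) == 0L) {
    stop_empty(sprintf("database %s has no MNXRef links to audit", db_label))
  }
  deg <- lengths(m2i)
  # distinct local IDs sitting in a shared group (robust when one local ID
  # carries several MNXRef identifiers)
  n_ids_multi <- length(unique(unlist(m2i[deg >= 2L], use.names = FALSE)))
  structure(
    list(db_label = db_label,
         n_ids = idx$n_ids,
         n_mnx = length(deg),
         mean_ids_per_mnx = mean(deg),
         sd_ids_per_mnx = spread_sd(deg, sd_type),
         n_mnx_multi = sum(deg >= 2L),
         pct_ids_multi = 100 * n_ids_multi / idx$n_ids,
         pct_mnx_multi = 100 * sum(deg >= 2L) / length(deg),
         max_ids_per_mnx = max(deg)),
    class = "mnx_link_stats")
}

#' Highest-degree names or identifiers
#'
#' Ranks names by the number of identifiers they link to
#' (`mode = "ambiguous-names"`) or identifiers by the number of names linked
#' to them (`mode = "multi-ids"`). Ordering is by count descending, ties
#' broken lexicographically by key, so rankings are reproducible.
#'
#' @inheritParams name_ambiguity
#' @param mode `"ambiguous-names"` or `"multi-ids"`.
#' @param k Number of entries to return (all entries when the namespace is
#'   smaller).
#' @return Data frame with columns `key` and `count`.
#' @export
top_entries <- function(index, mode = c("ambiguous-names", "multi-ids"), k = 10L) {
  mode <- match.arg(mode)
  if (!inherits(index, "namespace_index")) stop_usage("expected a namespace_index")
  if (!is.numeric(k) || length(k) != 1L || k < 1L) stop_usage("k must be >= 1")
  deg <- switch(mode,
                "ambiguous-names" = lengths(index$name_to_ids),
                "multi-ids" = lengths(index$id_to_names))
  keys <- names(deg)
  ord <- order_c(-deg, keys)
  take <- utils::head(ord, k)
  data.frame(key = keys[take], count = unname(deg[take]),
             stringsAsFactors = FALSE)
}

#' @export
print.ambiguity_stats <- function(x, ...) {
  cat(sprintf("%s: %d names, %.4f +/- %.3f IDs/name, %d ambiguous (%.2f%%), max %d\n",
              x$db_label, x$n_names, x$mean_ids_per_name, x$sd_ids_per_name,
              x$n_ambiguous, x$pct_ambiguous, x$max_ids_per_name))
  invisible(x)
}

#' @export
print.multiplicity_stats <- function(x, ...) {
  cat(sprintf("%s: %d IDs (%d named, %d unnamed), %.4f +/- %.3f names/ID, %d with >1 name (%.2f%%), max %d\n",
              x$db_label, x$n_ids, x$n_named_ids, x$n_unnamed,
              x$mean_names_per_id, x$sd_names_per_id, x$n_multi, x$pct_multi,
              x$max_multiplicity))
  invisible(x)
}

#' @export
print.mnx_link_stats <- function(x, ...) {
  cat(sprintf("%s: %d IDs, %d MNXRef IDs, %.4f +/- %.3f IDs/MNXRef, %d MNXRef IDs multi-linked, %.2f%% of IDs in shared groups\n",
              x$db_label, x$n_ids, x$n_mnx, x$mean_ids_per_mnx,
              x$sd_ids_per_mnx, x$n_mnx_multi, x$pct_ids_multi))
  invisible(x)
}
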