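new_finding <- function(kind, name, members, severity, chain = NULL,
                        db_pair = NULL, truncated = FALSE) {
  structure(list(kind = kind, name = name, members = members,
                 severity = severity, chain = chain, db_pair = db_pair,
                 truncated = truncated),
            class = "xref_finding")
}

# Members table for a set of (db, id) pairs: one row per identifier with its
# MNXRef identifiers and names carried as list columns.
members_frame <- function(collection, db, ids) {
  idx <- get_index(collection, db)
  out <- data.frame(db = rep(db, length(ids)), id = ids, stringsAsFactors = FALSE)
  out$mnx <- unname(lapply(ids, function(i) idx$id_to_mnx[[i]] %||% character(0)))
  out$names <- unname(lapply(ids, function(i) idx$id_to_names[[i]] %||% character(0)))
  out
}

distinct_mnx <- function(members) length(unique(unlist(members$mnx, use.names = FALSE)))

#' Ambiguous names pointing at different compounds within one database
#'
#' Emits one finding per name linked to two or more local identifiers whose
#' MNXRef identifier sets are not all identical. Names whose identifiers all
#' share one MNXRef identifier are deliberate merges (e.g. protonation-state
#' variants folded together) and are not reported. Every emitted finding has
#' at least two distinct MNXRef identifiers among its members.
#'
#' @param index A `namespace_index`.
#' @param collection Optional `namespace_collection` the index came from
#'   (only used to annotate members); defaults to a collection containing
#'   just `index`.
#' @return List of `xref_finding` objects (kind `"intra_ambiguous"`), sorted
#'   by severity descending then name.
#' @export
intra_ambiguous_findings <- function(index, collection = NULL) {
  if (!inherits(index, "namespace_index")) stop_usage("expected a namespace_index")
  if (is.null(collection)) {
    collection <- structure(
      list(indexes = stats::setNames(list(index), index$db_label),
           mnx_links = data.frame(db = character(0), id = character(0),
                                  mnx = character(0))),
      class = "namespace_collection")
  }
  findings <- list()
  for (nm in names(index$name_to_ids)) {
    ids <- index$name_to_ids[[nm]]
    if (length(ids) < 2L) next
    sets <- lapply(ids, function(i) index$id_to_mnx[[i]] %||% character(0))
    if (all(vapply(sets, identical, TRUE, y = sets[[1L]]))) next
    members <- members_frame(collection, index$db_label, ids)
    members$mnx <- sets
    sev <- distinct_mnx(members)
    if (sev < 2L) next
    findings[[length(findings) + 1L]] <-
      new_finding("intra_ambiguous", nm, members, sev)
  }
  sort_findings(findings)
}

#' Names linked to different compounds in two databases
#'
#' For every name present in both databases, compares the union of MNXRef
#' identifiers reachable from each side's identifiers under that name; a
#' finding is emitted when the two unions differ as sets (and at least two
#' distinct MNXRef identifiers are involved). This is the classic shared
#' abbreviation trap: "suc" meaning succinate in one database and sucrose in
#' another.
#'
#' @param collection A `namespace_collection`.
#' @param db_a,db_b Database prefixes.
#' @return List of `xref_finding` objects (kind `"cross_db_conflict"`),
#'   sorted by severity descending then name.
#' @export
cross_db_conflicts <- function(collection, db_a, db_b) {
  ia <- get_index(collection, db_a)
  ib <- get_index(collection, db_b)
  common <- intersect(names(ia$name_to_ids), names(ib$name_to_ids))
  findings <- list()
  for (nm in sort_c(common)) {
    ids_a <- ia$name_to_ids[[nm]]
    ids_b <- ib$name_to_ids[[nm]]
    mnx_a <- sort_c(unique(unlist(lapply(ids_a, function(i) ia$id_to_mnx[[i]]),
                                  use.names = FALSE)))
    mnx_b <- sort_c(unique(unlist(lapply(ids_b, function(i) ib$id_to_mnx[[i]]),
                                  use.names = FALSE)))
    if (identical(mnx_a, mnx_b)) next
    members <- rbind(members_frame(collection, db_a, ids_a),
                     members_frame(collection, db_b, ids_b))
    sev <- distinct_mnx(members)
    if (sev < 2L) next
    findings[[length(findings) + 1L]] <-
      new_finding("cross_db_conflict", nm, members, sev,
                  db_pair = c(db_a, db_b))
  }
  sort_findings(findings)
}

# Lexicographically smallest shortest path between two vertices of an
# unweighted graph: walk forward from s, always taking the smallest-named
# neighbour that still lies on some shortest s-t path.
lex_shortest_path <- function(g, s, t) {
  d_s <- igraph::distances(g, v = s)[1L, ]
  d_t <- igraph::distances(g, v = t)[1L, ]
  D <- d_s[[t]]
  path <- s
  cur <- s
  while (cur != t) {
    nb <- names(igraph::neighbors(g, cur))
    nb <- nb[d_s[nb] == d_s[[cur]] + 1 & d_s[nb] + d_t[nb] == D]
    cur <- sort_c(nb)[1L]
    path <- c(path, cur)
  }
  path
}

#' Synonym chains joining distinct compounds within one database
#'
#' Builds the bipartite graph whose vertices are local identifiers and
#' names, with an edge for every identifier-name link, and takes its
#' connected components. A component containing identifiers with two or
#' more distinct MNXRef identifiers means that chained synonym lookups can
#' silently walk from one compound to a different one (the pattern where a
#' shared opaque synonym makes "water" reachable from "pyruvate"). Each such
#' component yields one finding whose `chain` is a shortest alternating
#' id-name-id... path between two identifiers carrying different MNXRef
#' identifiers, ties broken lexicographically so reports are stable.
#'
#' @inheritParams intra_ambiguous_findings
#' @param max_path_length Maximum number of elements reported in a witness
#'   chain; longer witnesses are truncated (and flagged) but the component
#'   is still reported. Must be at least 3 (id, name, id).
#' @return List of `xref_finding` objects (kind `"synonym_chain"`), sorted
#'   by severity descending then first member identifier.
#' @export
synonym_chains <- function(index, max_path_length = 11L) {
  if (!inherits(index, "namespace_index")) stop_usage("expected a namespace_index")
  if (!is.numeric(max_path_length) || max_path_length < 3L) {
    stop_usage("max_path_length must be >= 3")
  }
  ids <- names(index$id_to_names)
  nm_links <- data.frame(
    id = rep(ids, lengths(index$id_to_names)),
    name = unlist(index$id_to_names, use.names = FALSE),
    stringsAsFactors = FALSE)
  if (nrow(nm_links) == 0L) return(list())
  edges <- rbind(paste0("i\r", nm_links$id), paste0("n\r", nm_links$name))
  g <- igraph::make_graph(as.vector(edges), directed = FALSE)
  g <- igraph::simplify(g)
  comp <- igraph::components(g)
  vnames <- igraph::V(g)$name
  findings <- list()
  for (ci in seq_len(comp$no)) {
    vs <- vnames[comp$membership == ci]
    c_ids <- sub("^i\r", "", vs[startsWith(vs, "i\r")])
    if (length(c_ids) < 2L) next
    sets <- lapply(c_ids, function(i) index$id_to_mnx[[i]] %||% character(0))
    names(sets) <- c_ids
    if (distinct_mnx(list(mnx = sets)) < 2L) next
    members <- members_frame_from_index(index, sort_c(c_ids))
    sev <- distinct_mnx(members)
    if (sev < 2L) next

    # witness: closest pair of identifiers with differing MNXRef sets,
    # smallest pair and path lexicographically
    sub <- igraph::induced_subgraph(g, vs)
    cand <- sort_c(c_ids[lengths(sets[c_ids]) > 0L])
    vert <- paste0("i\r", cand)
    dm <- igraph::distances(sub, v = vert, to = vert)
    best <- NULL
    for (ai in seq_along(cand)) {
      for (bi in seq_along(cand)) {
        if (bi <= ai) next
        if (identical(sets[[cand[ai]]], sets[[cand[bi]]])) next
        d <- dm[ai, bi]
        if (is.null(best) || d < best$d) best <- list(d = d, a = cand[ai], b = cand[bi])
      }
    }
    chain <- character(0)
    truncated <- FALSE
    if (!is.null(best)) {
      path <- lex_shortest_path(sub, paste0("i\r", best$a), paste0("i\r", best$b))
      chain <- sub("^[in]\r", "", path)
      if (length(chain) > max_path_length) {
        chain <- utils::head(chain, max_path_length)
        truncated <- TRUE
      }
    }
    findings[[length(findings) + 1L]] <-
      new_finding("synonym_chain", NA_character_, members, sev,
                  chain = chain, truncated = truncated)
  }
  sort_findings(findings)
}

members_frame_from_index <- function(index, ids) {
  out <- data.frame(db = rep(index$db_label, length(ids)), id = ids,
                    stringsAsFactors = FALSE)
  out$mnx <- unname(lapply(ids, function(i) index$id_to_mnx[[i]] %||% character(0)))
  out$names <- unname(lapply(ids, function(i) index$id_to_names[[i]] %||% character(0)))
  out
}

sort_findings <- function(findings) {
  if (length(findings) == 0L) return(findings)
  sev <- vapply(findings, function(f) f$severity, 0L)
  nm <- vapply(findings, function(f) {
    if (!is.na(f$name)) f$name else f$members$id[1L]
  }, "")
  # full member list as the final tie-break, so reports never depend on the
  # order in which detectors were run
  mem <- vapply(findings, function(f) {
    paste(f$kind, paste(f$members$db, f$members$id, collapse = ";"))
  }, "")
  findings[order_c(-sev, nm, mem)]
}

#' Render findings as a TSV or JSON document
#'
#' TSV output carries one row per finding member in the classic
#' inconsistency-table layout — Abbreviation, Database, IDs in Database,
#' MetaNetX ID, Compound(s) — followed by Kind, Severity and (for synonym
#' chains) the witness Chain. Output is deterministic: findings sorted by
#' severity descending then name, members in their stored (sorted) order.
#'
#' @param findings List of `xref_finding` objects (may mix kinds).
#' @param format `"tsv"` or `"json"`.
#' @return A single string holding the document.
#' @export
render_findings <- function(findings, format = c("tsv", "json")) {
  if (!is.character(format) || length(format) < 1L ||
      !all(format %in% c("tsv", "json"))) {
    stop_usage("format must be \"tsv\" or \"json\"")
  }
  format <- match.arg(format)
  findings <- sort_findings(findings)
  if (format == "json") {
    payload <- lapply(findings, function(f) {
      list(kind = f$kind,
           name = if (is.na(f$name)) NULL else f$name,
           severity = f$severity,
           members = lapply(seq_len(nrow(f$members)), function(i) {
             list(db = f$members$db[i], id = f$members$id[i],
                  mnx = as.list(f$members$mnx[[i]]),
                  names = as.list(f$members$names[[i]]))
           }),
           chain = if (is.null(f$chain)) NULL else as.list(f$chain),
           truncated = f$truncated)
    })
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null",
                                         pretty = TRUE)))
  }
  header <- paste(c("Abbreviation", "Database", "IDs in Database",
                    "MetaNetX ID", "Compound(s)", "Kind", "Severity", "Chain"),
                  collapse = "\t")
  rows <- character(0)
  for (f in findings) {
    chain_str <- if (is.null(f$chain) || length(f$chain) == 0L) "" else {
      paste0(paste(f$chain, collapse = " -> "), if (f$truncated) " ..." else "")
    }
    for (i in seq_len(nrow(f$members))) {
      nm_i <- f$members$names[[i]]
      compounds <- if (!is.na(f$name)) setdiff(nm_i, f$name) else nm_i
      rows <- c(rows, paste(
        c(if (is.na(f$name)) "" else f$name,
          f$members$db[i], f$members$id[i],
          paste(f$members$mnx[[i]], collapse = ";"),
          paste(compounds, collapse = ";"),
          f$kind, f$severity, chain_str),
        collapse = "\t"))
    }
  }
  paste(c(header, rows), collapse = "\n")
}

#' Read findings back from their JSON rendering
#'
#' @param text JSON produced by `render_findings(..., format = "json")`.
#' @return List of `xref_finding` objects.
#' @export
findings_from_json <- function(text) {
  payload <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  lapply(payload, function(p) {
    members <- data.frame(
      db = vapply(p$members, `[[`, "", "db"),
      id = vapply(p$members, `[[`, "", "id"),
      stringsAsFactors = FALSE)
    members$mnx <- lapply(p$members, function(m) as.character(unlist(m$mnx)))
    members$names <- lapply(p$members, function(m) as.character(unlist(m$names)))
    new_finding(p$kind, p$name %||% NA_character_, members,
                as.integer(p$severity),
                chain = if (is.null(p$chain)) NULL else as.character(unlist(p$chain)),
                truncated = isTRUE(p$truncated))
  })
}

#' @export
print.xref_finding <- function(x, ...) {
  lab <- if (!is.na(x$name)) sprintf("name %s", deparse(x$name)) else
    sprintf("component of %d IDs", nrow(x$members))
  cat(sprintf("[%s] %s: %d member(s), %d distinct MNXRef IDs\n",
              x$kind, lab, nrow(x$members), x$severity))
  invisible(x)
}
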