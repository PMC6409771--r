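# Independent brute-force oracles: plain loops over raw records, no use of
# the package's index structures, so they provide a second route for every
# audited quantity.

# Per-database union of names and MNXRef IDs per identifier, by iterating
# over the raw records.
oracle_db_links <- function(records, db) {
  ids <- unique(records$source_id[records$source_db == db])
  id_names <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  id_mnx <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  for (r in seq_len(nrow(records))) {
    if (records$source_db[r] != db) next
    i <- records$source_id[r]
    id_names[[i]] <- union(id_names[[i]], records$names[[r]])
    if (nzchar(records$mnx_id[r])) {
      id_mnx[[i]] <- union(id_mnx[[i]], records$mnx_id[r])
    }
  }
  list(ids = ids, id_names = id_names, id_mnx = id_mnx)
}

oracle_intra_counts <- function(records, db) {
  L <- oracle_db_links(records, db)
  all_names <- unique(unlist(L$id_names, use.names = FALSE))
  name_deg <- integer(length(all_names))
  for (k in seq_along(all_names)) {
    cnt <- 0L
    for (i in L$ids) if (all_names[k] %in% L$id_names[[i]]) cnt <- cnt + 1L
    name_deg[k] <- cnt
  }
  id_deg <- vapply(L$ids, function(i) length(L$id_names[[i]]), 0L)
  named <- id_deg[id_deg > 0L]
  all_mnx <- unique(unlist(L$id_mnx, use.names = FALSE))
  mnx_deg <- integer(length(all_mnx))
  for (k in seq_along(all_mnx)) {
    cnt <- 0L
    for (i in L$ids) if (all_mnx[k] %in% L$id_mnx[[i]]) cnt <- cnt + 1L
    mnx_deg[k] <- cnt
  }
  list(n_names = length(all_names),
       n_links = sum(name_deg),
       n_ambiguous = sum(name_deg >= 2L),
       max_ids_per_name = if (length(name_deg)) max(name_deg) else 0L,
       n_ids = length(L$ids),
       n_named_ids = length(named),
       n_unnamed = sum(id_deg == 0L),
       n_multi = sum(named >= 2L),
       max_multiplicity = if (length(named)) max(named) else 0L,
       n_mnx = length(all_mnx),
       n_mnx_multi = sum(mnx_deg >= 2L))
}

# All mapped identifier pairs between two databases, by comparing every
# source identifier with every target identifier.
oracle_map_pairs <- function(records, source_db, target_db, method) {
  A <- oracle_db_links(records, source_db)
  B <- oracle_db_links(records, target_db)
  src <- character(0)
  tgt <- character(0)
  for (i in A$ids) {
    keys_i <- if (method == "name") A$id_names[[i]] else A$id_mnx[[i]]
    for (j in B$ids) {
      keys_j <- if (method == "name") B$id_names[[j]] else B$id_mnx[[j]]
      if (length(intersect(keys_i, keys_j)) > 0L) {
        src <- c(src, i)
        tgt <- c(tgt, j)
      }
    }
  }
  data.frame(src = src, tgt = tgt, stringsAsFactors = FALSE)
}

oracle_map_counts <- function(records, source_db, target_db, method) {
  p <- oracle_map_pairs(records, source_db, target_db, method)
  per_src <- table(p$src)
  list(n_mapped = length(per_src), n_nonunique = sum(per_src >= 2L))
}

# Connected components of the within-database id/name bipartite graph by
# repeated frontier expansion; returns the components flagged as joining
# at least two distinct MNXRef identifiers.
oracle_flagged_components <- function(records, db) {
  L <- oracle_db_links(records, db)
  remaining <- L$ids
  flagged <- list()
  while (length(remaining) > 0L) {
    comp <- character(0)
    frontier <- remaining[1L]
    while (length(frontier) > 0L) {
      v <- frontier[1L]
      frontier <- frontier[-1L]
      if (v %in% comp) next
      comp <- c(comp, v)
      for (u in remaining) {
        if (!(u %in% comp) && !(u %in% frontier) &&
            length(intersect(L$id_names[[v]], L$id_names[[u]])) > 0L) {
          frontier <- c(frontier, u)
        }
      }
    }
    remaining <- setdiff(remaining, comp)
    if (length(comp) >= 2L &&
        length(unique(unlist(L$id_mnx[comp], use.names = FALSE))) >= 2L) {
      flagged[[length(flagged) + 1L]] <- sort(comp)
    }
  }
  flagged[order(vapply(flagged, `[`, "", 1L))]
}

# Pairs (src, tgt) implied by an id_mapping's entries.
mapping_pairs <- function(mapping) {
  sizes <- lengths(mapping$entries)
  data.frame(src = rep(names(mapping$entries), sizes),
             tgt = unlist(mapping$entries, use.names = FALSE),
             stringsAsFactors = FALSE)
}

sorted_pair_key <- function(df, flip = FALSE) {
  if (flip) {
    sort(paste(df$tgt, df$src, sep = "\r"))
  } else {
    sort(paste(df$src, df$tgt, sep = "\r"))
  }
}

# Small random record sets built independently of the synthetic generator:
# may contain duplicate records, repeated (id, name) links, nameless
# identifiers and cross-database name collisions.
random_records <- function(seed, n_db = 2L, ids_per_db = 8L) {
  set.seed(seed)
  dbs <- paste0("rdb", seq_len(n_db))
  pool <- sprintf("w%02d", 1:25) # small pool => frequent collisions
  rows_db <- character(0); rows_id <- character(0); rows_mnx <- character(0)
  names_l <- list()
  for (db in dbs) {
    for (i in seq_len(ids_per_db)) {
      id <- sprintf("%s_i%02d", db, i)
      reps <- sample(1:2, 1L) # some identifiers appear in two records
      for (r in seq_len(reps)) {
        k <- sample(0:3, 1L)
        rows_db <- c(rows_db, db)
        rows_id <- c(rows_id, id)
        rows_mnx <- c(rows_mnx, sprintf("MNXR%03d", sample(1:40, 1L)))
        names_l[[length(names_l) + 1L]] <-
          if (k == 0L) character(0) else sample(pool, k)
      }
    }
  }
  xref_records(rows_db, rows_id, rows_mnx, evidence = "rand", names = names_l)
}
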