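#' Configuration for the synthetic cross-reference generator
#'
#' The generator emulates the structure of a real multi-database metabolite
#' cross-reference snapshot: several database prefixes, a per-identifier
#' synonym-count (multiplicity) distribution, a controlled fraction of
#' ambiguous names, MNXRef identifiers shared across database pairs, and
#' planted cross-database name conflicts and within-database synonym
#' chains. Default values are chosen to sit inside the ranges observed in
#' public biochemical databases: mean multiplicity around 2 names per
#' identifier, 5% planted ambiguous names, 10% of identifiers per database
#' pair sharing a MNXRef identifier.
#'
#' @param n_databases Number of synthetic databases (`dbA`, `dbB`, ...; at
#'   least 2, at most 26).
#' @param ids_per_db Identifiers per database.
#' @param multiplicity_weights Named numeric vector of sampling weights for
#'   names-per-identifier; names are the multiplicities (e.g.
#'   `c("1" = .5, "2" = .3, "5" = .2)`).
#' @param ambiguous_name_fraction Fraction (of the base name count per
#'   database) of additional planted names each linking two identifiers of
#'   that database.
#' @param cross_db_shared_mnx_fraction Fraction of identifiers, per database
#'   pair, assigned a MNXRef identifier shared with one identifier of the
#'   other database.
#' @param n_cross_db_conflicts Number of planted cross-database conflicts
#'   (same name, different MNXRef identifiers, different databases).
#' @param n_chains Number of planted three-identifier synonym chains.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_databases = 6L, ids_per_db = 200L,
                             multiplicity_weights = c("1" = 0.5, "2" = 0.25,
                                                      "3" = 0.15, "5" = 0.10),
                             ambiguous_name_fraction = 0.05,
                             cross_db_shared_mnx_fraction = 0.10,
                             n_cross_db_conflicts = 5L, n_chains = 2L,
                             seed = 1L) {
  if (!is.numeric(n_databases) || n_databases < 2L || n_databases > 26L) {
    stop_config("n_databases must be between 2 and 26")
  }
  if (!is.numeric(ids_per_db) || ids_per_db < 1L) {
    stop_config("ids_per_db must be >= 1")
  }
  w <- multiplicity_weights
  if (is.null(names(w)) || any(is.na(suppressWarnings(as.integer(names(w))))) ||
      any(w < 0) || sum(w) <= 0 || any(as.integer(names(w)) < 1L)) {
    stop_config("multiplicity_weights must be non-negative weights named by multiplicities >= 1")
  }
  for (f in c(ambiguous_name_fraction, cross_db_shared_mnx_fraction)) {
    if (!is.numeric(f) || f < 0 || f > 1) stop_config("fractions must lie in [0, 1]")
  }
  if (n_cross_db_conflicts < 0L || n_chains < 0L) {
    stop_config("planted structure counts must be >= 0")
  }
  cfg <- list(n_databases = as.integer(n_databases),
              ids_per_db = as.integer(ids_per_db),
              multiplicity_weights = w,
              ambiguous_name_fraction = ambiguous_name_fraction,
              cross_db_shared_mnx_fraction = cross_db_shared_mnx_fraction,
              n_cross_db_conflicts = as.integer(n_cross_db_conflicts),
              n_chains = as.integer(n_chains),
              seed = as.integer(seed))
  # feasibility: every database must have enough identifiers left over for
  # the planted structures after MNXRef sharing reserves its quota
  k_share <- round(cfg$cross_db_shared_mnx_fraction * cfg$ids_per_db)
  reserved <- (cfg$n_databases - 1L) * k_share +
    cfg$n_cross_db_conflicts + # worst case: one database in every conflict
    3L * ceiling(cfg$n_chains / cfg$n_databases) +
    if (cfg$ambiguous_name_fraction > 0) 2L else 0L
  if (reserved > cfg$ids_per_db) {
    stop_config(sprintf(
      "infeasible configuration: planted structures need up to %d identifiers per database but only %d exist",
      reserved, cfg$ids_per_db))
  }
  structure(cfg, class = "synthetic_config")
}

# --- ground-truth recounts -------------------------------------------------
# These operate directly on the generator's raw link tables (data frame
# joins and tabulations); they never touch build_indexes() or the audit
# functions, so recovery tests compare two genuinely independent routes.

truth_ambiguity <- function(nl_db) {
  deg <- table(nl_db$name)
  list(n_names = length(deg),
       mean_ids_per_name = mean(as.vector(deg)),
       n_ambiguous = sum(deg >= 2L),
       max_ids_per_name = max(as.vector(deg)))
}

truth_multiplicity <- function(nl_db, all_ids) {
  deg <- table(nl_db$id)
  list(n_ids = length(all_ids),
       n_named_ids = length(deg),
       mean_names_per_id = mean(as.vector(deg)),
       n_multi = sum(deg >= 2L),
       max_multiplicity = max(as.vector(deg)),
       n_unnamed = length(all_ids) - length(deg))
}

truth_mnx <- function(ml_db, all_ids) {
  deg <- table(ml_db$mnx)
  multi <- names(deg)[deg >= 2L]
  list(n_ids = length(all_ids),
       n_mnx = length(deg),
       mean_ids_per_mnx = mean(as.vector(deg)),
       n_mnx_multi = length(multi),
       n_ids_multi = length(unique(ml_db$id[ml_db$mnx %in% multi])),
       max_ids_per_mnx = max(as.vector(deg)))
}

truth_pairwise <- function(links, dbs, keycol) {
  rows <- list()
  for (s in dbs) {
    for (t in dbs) {
      if (s == t) next
      a <- links[links$db == s, c("id", keycol)]
      b <- links[links$db == t, c("id", keycol)]
      m <- merge(a, b, by = keycol, suffixes = c("_s", "_t"))
      per_src <- tapply(m$id_t, m$id_s, function(x) length(unique(x)))
      rows[[length(rows) + 1L]] <- data.frame(
        source_db = s, target_db = t,
        n_mapped = length(per_src),
        n_nonunique = sum(per_src >= 2L),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic cross-reference table with known ground truth
#'
#' Builds, deterministically from the seed, a record set whose ambiguity,
#' multiplicity, MNXRef-sharing and conflict structure is planted and then
#' recounted directly from the generator's own link tables — never through
#' the audit code — so audits can be validated against an independent
#' expectation. Base names and MNXRef identifiers come from collision-free
#' pools (`syn000001...`, `MNXS000001...`); the only collisions are the
#' planted ones.
#'
#' @param config A [synthetic_config()].
#' @return List with `records` (an `xref_records` data frame, one row per
#'   identifier) and `truth`, containing per-database expected statistics
#'   (`ambiguity`, `multiplicity`, `mnx`), `pairwise` expected mapped /
#'   non-unique counts for both methods, the planted `conflicts`
#'   (name, databases, MNXRef identifiers) and `chains` (database,
#'   identifiers, bridge names).
#' @export
generate_xref <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, as.list(config))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  dbs <- paste0("db", LETTERS[seq_len(config$n_databases)])
  name_ctr <- 0L
  mnx_ctr <- 0L
  new_names <- function(k) {
    out <- sprintf("syn%06d", name_ctr + seq_len(k))
    name_ctr <<- name_ctr + k
    out
  }
  new_mnx <- function(k = 1L) {
    out <- sprintf("MNXS%06d", mnx_ctr + seq_len(k))
    mnx_ctr <<- mnx_ctr + k
    out
  }

  ids <- lapply(dbs, function(db) sprintf("%s_%04d", db, seq_len(config$ids_per_db)))
  names(ids) <- dbs
  id_names <- list() # db -> named list id -> character names
  id_mnx <- list()   # db -> named character id -> mnx
  mults <- as.integer(names(config$multiplicity_weights))
  for (db in dbs) {
    m <- mults[sample.int(length(mults), config$ids_per_db, replace = TRUE,
                          prob = config$multiplicity_weights)]
    nm <- lapply(m, new_names)
    names(nm) <- ids[[db]]
    id_names[[db]] <- nm
    id_mnx[[db]] <- stats::setNames(new_mnx(config$ids_per_db), ids[[db]])
  }
  available <- ids # identifiers not yet consumed by a planted structure

  take <- function(db, k) {
    pool <- available[[db]]
    if (length(pool) < k) {
      stop_config(sprintf("infeasible configuration: database %s ran out of identifiers", db))
    }
    picked <- sort_c(sample(pool, k))
    available[[db]] <<- setdiff(pool, picked)
    picked
  }

  # planted cross-database MNXRef sharing: per unordered pair, k_share
  # identifier couples get one common fresh MNXRef identifier
  k_share <- round(config$cross_db_shared_mnx_fraction * config$ids_per_db)
  if (config$n_databases >= 2L && k_share > 0L) {
    pair_idx <- utils::combn(dbs, 2L)
    for (p in seq_len(ncol(pair_idx))) {
      a <- pair_idx[1L, p]; b <- pair_idx[2L, p]
      ids_a <- take(a, k_share)
      ids_b <- take(b, k_share)
      shared <- new_mnx(k_share)
      id_mnx[[a]][ids_a] <- shared
      id_mnx[[b]][ids_b] <- shared
    }
  }

  # planted cross-database name conflicts: one shared name between two
  # identifiers of different databases that keep their distinct MNXRef IDs
  conflicts <- list()
  if (config$n_cross_db_conflicts > 0L) {
    pair_idx <- utils::combn(dbs, 2L)
    for (cfl in seq_len(config$n_cross_db_conflicts)) {
      p <- ((cfl - 1L) %% ncol(pair_idx)) + 1L
      a <- pair_idx[1L, p]; b <- pair_idx[2L, p]
      id_a <- take(a, 1L)
      id_b <- take(b, 1L)
      cname <- sprintf("conflict%03d", cfl)
      id_names[[a]][[id_a]] <- c(id_names[[a]][[id_a]], cname)
      id_names[[b]][[id_b]] <- c(id_names[[b]][[id_b]], cname)
      conflicts[[cfl]] <- list(name = cname, dbs = c(a, b),
                               ids = c(id_a, id_b),
                               mnx = unname(c(id_mnx[[a]][id_a], id_mnx[[b]][id_b])))
    }
  }

  # planted synonym chains: three reserved identifiers of one database
  # joined by two bridge names (id1 - bridge1 - id2 - bridge2 - id3)
  chains <- list()
  if (config$n_chains > 0L) {
    for (ch in seq_len(config$n_chains)) {
      db <- dbs[((ch - 1L) %% length(dbs)) + 1L]
      trio <- take(db, 3L)
      b1 <- sprintf("bridge%03da", ch)
      b2 <- sprintf("bridge%03db", ch)
      id_names[[db]][[trio[1L]]] <- c(id_names[[db]][[trio[1L]]], b1)
      id_names[[db]][[trio[2L]]] <- c(id_names[[db]][[trio[2L]]], b1, b2)
      id_names[[db]][[trio[3L]]] <- c(id_names[[db]][[trio[3L]]], b2)
      chains[[ch]] <- list(db = db, ids = trio, bridge_names = c(b1, b2))
    }
  }

  # planted intra-database ambiguity: extra names, each linking two
  # identifiers drawn from the untouched pool
  ambiguous_planted <- stats::setNames(vector("list", length(dbs)), dbs)
  for (db in dbs) {
    n_base <- sum(lengths(id_names[[db]]))
    k_amb <- round(config$ambiguous_name_fraction * n_base)
    if (k_amb == 0L) {
      ambiguous_planted[[db]] <- character(0)
      next
    }
    pool <- available[[db]]
    if (length(pool) < 2L) {
      stop_config(sprintf(
        "infeasible configuration: database %s has no identifier pair left for planted ambiguity", db))
    }
    planted <- character(k_amb)
    for (j in seq_len(k_amb)) {
      pair <- sample(pool, 2L)
      aname <- sprintf("amb%s%04d", db, j)
      id_names[[db]][[pair[1L]]] <- c(id_names[[db]][[pair[1L]]], aname)
      id_names[[db]][[pair[2L]]] <- c(id_names[[db]][[pair[2L]]], aname)
      planted[j] <- aname
    }
    ambiguous_planted[[db]] <- planted
  }

  # assemble records (one per identifier, database order then id order)
  rec_db <- rep(dbs, each = config$ids_per_db)
  rec_id <- unlist(ids, use.names = FALSE)
  rec_names <- unlist(lapply(dbs, function(db) unname(id_names[[db]])),
                      recursive = FALSE)
  rec_mnx <- unlist(lapply(dbs, function(db) unname(id_mnx[[db]])), use.names = FALSE)
  records <- xref_records(rec_db, rec_id, rec_mnx, evidence = "synthetic",
                          names = rec_names)

  # ground truth by direct counting over the final record link lists
  nl <- data.frame(db = rep(records$source_db, lengths(records$names)),
                   id = rep(records$source_id, lengths(records$names)),
                   name = unlist(records$names, use.names = FALSE),
                   stringsAsFactors = FALSE)
  ml <- data.frame(db = records$source_db, id = records$source_id,
                   mnx = records$mnx_id, stringsAsFactors = FALSE)
  per_db <- lapply(dbs, function(db) {
    list(ambiguity = truth_ambiguity(nl[nl$db == db, ]),
         multiplicity = truth_multiplicity(nl[nl$db == db, ], ids[[db]]),
         mnx = truth_mnx(ml[ml$db == db, ], ids[[db]]))
  })
  names(per_db) <- dbs
  pw_name <- truth_pairwise(nl, dbs, "name")
  pw_name$method <- "name"
  ml_key <- ml; names(ml_key)[names(ml_key) == "mnx"] <- "key"
  pw_mnx <- truth_pairwise(ml_key, dbs, "key")
  pw_mnx$method <- "mnx"

  truth <- list(per_db = per_db,
                pairwise = rbind(pw_name, pw_mnx),
                conflicts = conflicts,
                chains = chains,
                ambiguous_planted = ambiguous_planted)
  list(records = records, truth = truth, config = config)
}
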