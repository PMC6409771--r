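# Abbreviation-only slice of the conflict examples: four MetaCyc
# identifiers carrying just their shorthand names.
metacyc_slice <- function() {
  xref_records("MetaCyc", c("SUC", "PROTON", "HIS", "CPD-610"),
               c("MNXM25", "MNXM1", "MNXM134", "MNXM88031"),
               names = list("suc", "H", "H", "tmp"))
}

test_that("ambiguity statistics match a hand count on the abbreviation slice", {
  idx <- build_indexes(metacyc_slice())$indexes$MetaCyc
  a <- name_ambiguity(idx)
  expect_equal(a$n_names, 3L)
  expect_equal(a$mean_ids_per_name, 4 / 3)
  expect_equal(a$n_ambiguous, 1L)
  expect_equal(a$pct_ambiguous, 100 / 3)
  expect_equal(a$max_ids_per_name, 2L)
  # population sd of degrees (1, 2, 1)
  expect_equal(a$sd_ids_per_name, sqrt(2 / 9))
  expect_equal(name_ambiguity(idx, sd_type = "sample")$sd_ids_per_name,
               stats::sd(c(1, 2, 1)))
})

test_that("an identifier with the water synonyms has multiplicity 2", {
  recs <- xref_records("kegg", "C00001", "MNXM2", names = list(c("water", "H20")))
  m <- id_multiplicity(build_indexes(recs)$indexes$kegg)
  expect_equal(m$mean_names_per_id, 2)
  expect_equal(m$max_multiplicity, 2L)
  expect_equal(m$n_multi, 1L)
})

test_that("a strictly one-to-one namespace shows no ambiguity or multiplicity", {
  recs <- xref_records("bigg", sprintf("id%d", 1:5), sprintf("MNXM%d", 1:5),
                       names = as.list(sprintf("name%d", 1:5)))
  idx <- build_indexes(recs)$indexes$bigg
  a <- name_ambiguity(idx)
  m <- id_multiplicity(idx)
  expect_equal(a$mean_ids_per_name, 1)
  expect_equal(a$sd_ids_per_name, 0)
  expect_equal(a$pct_ambiguous, 0)
  expect_equal(m$mean_names_per_id, 1)
  expect_equal(m$sd_names_per_id, 0)
  expect_equal(m$pct_multi, 0)
})

test_that("a single name shared by k identifiers is fully ambiguous", {
  k <- 4L
  recs <- xref_records("db1", sprintf("id%d", 1:k), sprintf("MNXM%d", 1:k),
                       names = as.list(rep("shared", k)))
  a <- name_ambiguity(build_indexes(recs)$indexes$db1)
  expect_equal(a$mean_ids_per_name, k)
  expect_equal(a$max_ids_per_name, k)
  expect_equal(a$pct_ambiguous, 100)
})

test_that("nameless identifiers are tallied apart and leave the mean untouched", {
  recs <- xref_records("db1", c("a", "b", "c"), sprintf("MNXM%d", 1:3),
                       names = list(c("x", "y"), "z", character(0)))
  m <- id_multiplicity(build_indexes(recs)$indexes$db1)
  expect_equal(m$n_ids, 3L)
  expect_equal(m$n_named_ids, 2L)
  expect_equal(m$n_unnamed, 1L)
  expect_equal(m$mean_names_per_id, 1.5)
})

test_that("empty namespaces raise a classed error instead of silent zeros", {
  recs <- xref_records("db1", "a", "MNXM1", names = list(character(0)))
  idx <- build_indexes(recs)$indexes$db1
  expect_error(name_ambiguity(idx), class = "xref_empty_namespace_error")
  nomnx <- xref_records("db1", "a", "", names = list("x"))
  expect_error(mnx_link_stats(build_indexes(nomnx), "db1"),
               class = "xref_empty_namespace_error")
})

test_that("MNXRef-link statistics match hand counts", {
  coll <- build_indexes(metacyc_slice())
  x <- mnx_link_stats(coll, "MetaCyc")
  expect_equal(x$n_ids, 4L)
  expect_equal(x$n_mnx, 4L)
  expect_equal(x$mean_ids_per_mnx, 1)
  expect_equal(x$n_mnx_multi, 0L)
  expect_equal(x$pct_ids_multi, 0)
  merged <- xref_records("db1", c("a", "b", "c"), rep("MNXM7", 3),
                         names = list("n1", "n2", "n3"))
  y <- mnx_link_stats(build_indexes(merged), "db1")
  expect_equal(y$mean_ids_per_mnx, 3)
  expect_equal(y$max_ids_per_mnx, 3L)
  expect_equal(y$pct_ids_multi, 100)
  expect_equal(y$pct_mnx_multi, 100)
  expect_error(mnx_link_stats(coll, "Nope"), class = "xref_lookup_error")
})

test_that("rankings are ordered by degree with a lexicographic tie-break", {
  idx <- build_indexes(metacyc_slice())$indexes$MetaCyc
  top1 <- top_entries(idx, "ambiguous-names", 1L)
  expect_equal(top1$key, "H")
  expect_equal(top1$count, 2L)
  all_entries <- top_entries(idx, "ambiguous-names", 100L)
  expect_equal(nrow(all_entries), 3L) # k larger than the namespace
  expect_equal(all_entries$key, c("H", "suc", "tmp")) # ties lexicographic
  ids_rank <- top_entries(idx, "multi-ids", 4L)
  expect_equal(ids_rank$key, c("CPD-610", "HIS", "PROTON", "SUC"))
  expect_error(top_entries(idx, "multi-ids", 0L), class = "xref_usage_error")
})

test_that("the link-count conservation identity holds on every instance", {
  for (seed in 1:15) {
    recs <- random_records(seed, n_db = 2L, ids_per_db = 10L)
    for (idx in build_indexes(recs)$indexes) {
      a <- name_ambiguity(idx)
      m <- id_multiplicity(idx)
      expect_equal(a$n_names * a$mean_ids_per_name,
                   m$n_named_ids * m$mean_names_per_id)
      expect_equal(a$n_names * a$mean_ids_per_name, idx$n_links)
    }
  }
})

test_that("adding a link never decreases ambiguity measures", {
  for (seed in 1:10) {
    recs <- random_records(seed, n_db = 1L, ids_per_db = 8L)
    idx <- build_indexes(recs)$indexes[[1]]
    a0 <- name_ambiguity(idx)
    set.seed(seed + 1000)
    extra_id <- sample(recs$source_id, 1L)
    extra_name <- sample(unique(unlist(recs$names)), 1L)
    aug <- rbind(recs, xref_records(recs$source_db[1], extra_id, "MNXR999",
                                    names = list(extra_name)))
    class(aug) <- class(recs)
    a1 <- name_ambiguity(build_indexes(aug)$indexes[[1]])
    expect_gte(a1$mean_ids_per_name, a0$mean_ids_per_name)
    expect_gte(a1$n_ambiguous, a0$n_ambiguous)
    expect_gte(a1$max_ids_per_name, a0$max_ids_per_name)
  }
})

test_that("indexed statistics agree with the brute-force recount", {
  for (seed in 1:10) {
    recs <- random_records(seed, n_db = 2L, ids_per_db = 8L)
    coll <- build_indexes(recs)
    for (db in names(coll$indexes)) {
      o <- oracle_intra_counts(recs, db)
      a <- name_ambiguity(coll$indexes[[db]])
      m <- id_multiplicity(coll$indexes[[db]])
      x <- mnx_link_stats(coll, db)
      expect_equal(a$n_names, o$n_names)
      expect_equal(a$n_ambiguous, o$n_ambiguous)
      expect_equal(a$max_ids_per_name, o$max_ids_per_name)
      expect_equal(m$n_ids, o$n_ids)
      expect_equal(m$n_multi, o$n_multi)
      expect_equal(m$n_unnamed, o$n_unnamed)
      expect_equal(x$n_mnx, o$n_mnx)
      expect_equal(x$n_mnx_multi, o$n_mnx_multi)
    }
  }
})
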