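coll9 <- build_indexes(xref_conflict_examples())

test_that("ambiguous names pointing at different compounds are flagged within a database", {
  f <- intra_ambiguous_findings(coll9$indexes$MetaCyc, coll9)
  expect_length(f, 1L)
  expect_equal(f[[1]]$name, "H")
  expect_equal(sort(f[[1]]$members$id), c("HIS", "PROTON"))
  expect_equal(sort(unlist(f[[1]]$members$mnx)), c("MNXM1", "MNXM134"))
  expect_equal(f[[1]]$severity, 2L)
})

test_that("a shared name whose identifiers share one MNXRef ID is a merge, not a finding", {
  recs <- xref_records("db1", c("cit", "citr"), c("MNXM131", "MNXM131"),
                       names = list("citrate", "citrate"))
  expect_length(intra_ambiguous_findings(build_indexes(recs)$indexes$db1), 0L)
  unique_names <- xref_records("db1", c("a", "b"), c("MNXM1", "MNXM2"),
                               names = list("x", "y"))
  expect_length(intra_ambiguous_findings(build_indexes(unique_names)$indexes$db1), 0L)
})

test_that("cross-database conflicts surface the classic abbreviation clashes", {
  suc <- cross_db_conflicts(coll9, "MetaCyc", "Reactome")
  expect_equal(sort(vapply(suc, `[[`, "", "name")), c("PPP", "suc"))
  suc_f <- suc[[which(vapply(suc, `[[`, "", "name") == "suc")]]
  expect_equal(sort(unlist(suc_f$members$mnx)), c("MNXM167", "MNXM25"))
  tmp <- cross_db_conflicts(coll9, "KEGG", "MetaCyc")
  expect_equal(vapply(tmp, `[[`, "", "name"), "tmp")
  expect_equal(sort(unlist(tmp[[1]]$members$mnx)), c("MNXM662", "MNXM88031"))
  agree <- xref_records(c("d1", "d2"), c("x", "y"), c("MNXM5", "MNXM5"),
                        names = list("water", "water"))
  expect_length(cross_db_conflicts(build_indexes(agree), "d1", "d2"), 0L)
})

test_that("synonym chains join distinct compounds through shared opaque names", {
  # two Reactome-style entries joined by an opaque participant synonym
  recs <- xref_records("Reactome", c("r1", "r2"), c("MNXM2", "MNXM11"),
                       names = list(c("water", "H2O", "phys-ent-participant60981"),
                                    c("phys-ent-participant60981", "diphosphate")))
  f <- synonym_chains(build_indexes(recs)$indexes$Reactome)
  expect_length(f, 1L)
  expect_equal(f[[1]]$chain, c("r1", "phys-ent-participant60981", "r2"))
  expect_equal(sort(f[[1]]$members$id), c("r1", "r2"))
  expect_equal(f[[1]]$severity, 2L)
  # disconnected one-identifier components are never findings
  solo <- xref_records("db1", c("a", "b"), c("MNXM1", "MNXM2"),
                       names = list("x", "y"))
  expect_length(synonym_chains(build_indexes(solo)$indexes$db1), 0L)
})

test_that("long witness chains are truncated but the component is still reported", {
  n <- 5L
  ids <- sprintf("id%d", 1:n)
  nm <- lapply(seq_len(n), function(i) {
    c(if (i > 1L) sprintf("link%d", i - 1L), sprintf("link%d", i))
  })
  nm[[n]] <- sprintf("link%d", n - 1L)
  # only the endpoints carry MNXRef identifiers, so the shortest witness
  # between differing compounds must traverse the whole chain
  recs <- xref_records("db1", ids, c("MNXM1", "", "", "", "MNXM9"),
                       names = nm)
  full <- synonym_chains(build_indexes(recs)$indexes$db1, max_path_length = 20L)
  expect_length(full, 1L)
  expect_false(full[[1]]$truncated)
  expect_length(full[[1]]$chain, 9L) # id-name-id-... across all five identifiers
  short <- synonym_chains(build_indexes(recs)$indexes$db1, max_path_length = 3L)
  expect_length(short, 1L)
  expect_true(short[[1]]$truncated)
  expect_length(short[[1]]$chain, 3L)
  expect_error(synonym_chains(build_indexes(recs)$indexes$db1, 2L),
               class = "xref_usage_error")
})

test_that("every emitted finding joins at least two distinct MNXRef identifiers", {
  for (seed in 1:8) {
    recs <- random_records(seed, n_db = 2L, ids_per_db = 7L)
    coll <- build_indexes(recs)
    dbs <- names(coll$indexes)
    all_f <- c(intra_ambiguous_findings(coll$indexes[[1]], coll),
               cross_db_conflicts(coll, dbs[1], dbs[2]),
               synonym_chains(coll$indexes[[1]]))
    for (f in all_f) {
      expect_gte(f$severity, 2L)
      expect_gte(nrow(f$members), 2L)
      expect_gte(length(unique(unlist(f$members$mnx))), 2L)
    }
  }
})

test_that("flagged components equal the brute-force component enumeration", {
  for (seed in 1:8) {
    recs <- random_records(seed, n_db = 2L, ids_per_db = 7L)
    coll <- build_indexes(recs)
    for (db in names(coll$indexes)) {
      impl <- synonym_chains(coll$indexes[[db]])
      impl_sets <- lapply(impl, function(f) sort(f$members$id))
      impl_sets <- impl_sets[order(vapply(impl_sets, `[`, "", 1L))]
      expect_equal(impl_sets, oracle_flagged_components(recs, db))
    }
  }
})

test_that("rendered reports are deterministic and carry the conflict layout", {
  dbs <- names(coll9$indexes)
  findings <- list()
  for (i in seq_along(dbs)) {
    findings <- c(findings, intra_ambiguous_findings(coll9$indexes[[i]], coll9))
    for (j in seq_along(dbs)) {
      if (j > i) findings <- c(findings, cross_db_conflicts(coll9, dbs[i], dbs[j]))
    }
  }
  tsv <- render_findings(findings, "tsv")
  expect_identical(tsv, render_findings(rev(findings), "tsv")) # order-insensitive
  lines <- strsplit(tsv, "\n")[[1]]
  expect_match(lines[1], "^Abbreviation\tDatabase\tIDs in Database\tMetaNetX ID\tCompound\\(s\\)")
  suc_lines <- grep("^suc\t", lines, value = TRUE)
  expect_length(suc_lines, 2L)
  expect_true(any(grepl("MNXM25", suc_lines)) && any(grepl("MNXM167", suc_lines)))
  expect_error(render_findings(findings, "xml"), class = "xref_usage_error")
})

test_that("findings survive a JSON round trip", {
  findings <- c(intra_ambiguous_findings(coll9$indexes$MetaCyc, coll9),
                cross_db_conflicts(coll9, "MetaCyc", "Reactome"),
                synonym_chains(coll9$indexes$MetaCyc))
  js <- render_findings(findings, "json")
  back <- findings_from_json(js)
  expect_length(back, length(findings))
  essence <- function(fl) {
    out <- lapply(fl, function(f) {
      list(f$kind, f$name, f$severity, f$members$db, f$members$id,
           f$members$mnx, f$members$names, f$chain)
    })
    out[order(vapply(fl, `[[`, "", "kind"),
              vapply(fl, function(f) f$members$id[1], ""))]
  }
  expect_equal(essence(back), essence(findings))
})

test_that("an empty findings list renders to a header-only document", {
  expect_equal(strsplit(render_findings(list(), "tsv"), "\n")[[1]] |> length(), 1L)
  expect_equal(findings_from_json(render_findings(list(), "json")), list())
})
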