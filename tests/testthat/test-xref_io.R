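test_that("parsing splits columns, prefixes and synonym lists correctly", {
  lines <- c(
    "#source\tmnx_id\tevidence\tdescription",
    "bigg:10fthf\tMNXM237\tidentity\t10-Formyltetrahydrofolate",
    "kegg:C00001\tMNXM2\tidentity\twater|H2O",
    "",
    "chebi:15377\tMNXM2\tidentity\t water | H2O |water")
  recs <- parse_xref(lines)
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$source_db, c("bigg", "kegg", "chebi"))
  expect_equal(recs$source_id[1], "10fthf")
  expect_equal(recs$mnx_id[1], "MNXM237")
  expect_equal(recs$names[[1]], "10-Formyltetrahydrofolate")
  # separator splits names; trimming and within-record dedup applied
  expect_equal(recs$names[[2]], c("water", "H2O"))
  expect_equal(recs$names[[3]], c("water", "H2O"))
  rep <- attr(recs, "parse_report")
  expect_equal(rep$n_comments, 1L)
  expect_equal(rep$n_records, 3L)
})

test_that("first column splits at the first prefix separator only", {
  recs <- parse_xref("seed:cpd:weird\tMNXM9\tev\tx")
  expect_equal(recs$source_db, "seed")
  expect_equal(recs$source_id, "cpd:weird")
})

test_that("short lines fail with the line number; unprefixed rows are skipped with a warning", {
  expect_error(parse_xref(c("a:b\tMNXM1\tev\tx", "justonecolumn")),
               "line 2", class = "xref_parse_error")
  expect_warning(recs <- parse_xref(c("a:b\tMNXM1\tev\tx", "noprefix\tMNXM2")),
                 "prefix separator")
  expect_equal(nrow(recs), 1L)
  expect_equal(attr(recs, "parse_report")$n_skipped_no_prefix, 1L)
})

test_that("a non-default dialect round-trips", {
  d <- xref_dialect(comment_prefix = "%", column_separator = ",",
                    name_separator = ";", prefix_separator = "@")
  recs <- xref_records("kegg", "C00022", "MNXM23", "ev",
                       names = list(c("pyruvate", "2-oxopropanoate")))
  lines <- write_xref(recs, dialect = d)
  back <- parse_xref(lines, d)
  expect_equal(back$source_id, "C00022")
  expect_equal(back$names[[1]], c("pyruvate", "2-oxopropanoate"))
  expect_error(xref_dialect(name_separator = "\t"), class = "xref_config_error")
  expect_error(xref_dialect(comment_prefix = ""), class = "xref_config_error")
})

test_that("filters drop by local-ID prefix, compound name and self-reference, in that order", {
  recs <- xref_records(
    source_db = c("bigg", "bigg", "kegg", "seed", "mnx", "bigg"),
    source_id = c("M_10fthf", "10fthf", "C00103", "cpd11416", "MNXM1", "M_x"),
    mnx_id = sprintf("MNXM%d", 1:6),
    names = list("10-Formyltetrahydrofolate", "10-Formyltetrahydrofolate",
                 "D-Glucose 1-phosphate", "Biomass", "PROTON", "Biomass"))
  out <- apply_filters(recs)
  # bigg:M_ duplicates, the biomass compound, and the MetaNetX self-row go;
  # the record matching both the prefix and the name rule is blamed on the
  # first rule
  expect_equal(out$report$records_in, 6L)
  expect_equal(out$report$records_out, 2L)
  expect_equal(unname(out$report$dropped_by_rule),
               c(2L, 1L, 1L))
  expect_equal(out$records$source_id, c("10fthf", "C00103"))
  # conservation and idempotence
  expect_equal(out$report$records_in,
               out$report$records_out + sum(out$report$dropped_by_rule))
  twice <- apply_filters(out$records)
  expect_equal(twice$records, out$records)
  expect_equal(sum(twice$report$dropped_by_rule), 0L)
})

test_that("name filtering is whole-name case-insensitive, not substring", {
  recs <- xref_records("kegg", c("C1", "C2"), c("MNXM1", "MNXM2"),
                       names = list("BIOMASS", "biomass precursor"))
  out <- apply_filters(recs)
  expect_equal(out$records$source_id, "C2")
})

test_that("the literal-M prefix variant is available through configuration", {
  recs <- xref_records("bigg", c("Mg2", "atp"), c("MNXM1", "MNXM3"),
                       names = list("magnesium", "ATP"))
  default_kept <- apply_filters(recs)$records$source_id
  expect_equal(default_kept, c("Mg2", "atp")) # "M_" does not hit bare M ids
  strict <- apply_filters(recs, filter_config(drop_local_id_prefixes = list(bigg = "M")))
  expect_equal(strict$records$source_id, "atp")
})

test_that("empty input filters to an empty output with a zeroed report", {
  recs <- xref_records(character(0), character(0), character(0), names = list())
  out <- apply_filters(recs)
  expect_equal(out$report$records_in, 0L)
  expect_equal(nrow(out$records), 0L)
  expect_equal(sum(out$report$dropped_by_rule), 0L)
})

test_that("writing then parsing is the identity on record collections", {
  for (seed in 1:10) {
    recs <- random_records(seed, n_db = 2L, ids_per_db = 5L)
    back <- parse_xref(write_xref(recs))
    attr(back, "parse_report") <- NULL
    expect_identical(as.data.frame(back), as.data.frame(recs))
  }
  fixture <- xref_conflict_examples()
  lines <- write_xref(fixture)
  expect_length(lines, 11L) # header + 10 data lines
  back <- parse_xref(lines)
  attr(back, "parse_report") <- NULL
  expect_identical(as.data.frame(back), as.data.frame(fixture))
})

test_that("empty collections write a header-only file and reserved characters are refused", {
  empty <- xref_records(character(0), character(0), character(0), names = list())
  expect_length(write_xref(empty), 1L)
  bad <- xref_records("kegg", "C1", "MNXM1", names = list("a|b"))
  expect_error(write_xref(bad), class = "xref_serialize_error")
  bad2 <- xref_records("kegg", "C\t1", "MNXM1", names = list("x"))
  expect_error(write_xref(bad2), class = "xref_serialize_error")
})
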