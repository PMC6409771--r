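#' Curated cross-reference records illustrating classic mapping conflicts
#'
#' Ten real cross-reference entries, transcribed from public biochemical
#' databases, in which shared abbreviations join distinct compounds: "suc"
#' is succinate in MetaCyc but sucrose in Reactome; "H" is both the proton
#' and L-histidine within MetaCyc; "tmp" denotes four different phosphate
#' compounds across BiGG, ChEBI, KEGG and MetaCyc; and "PPP" is the
#' triphosphate ion in Reactome but a piperidine derivative in MetaCyc.
#' Each record carries the abbreviation and the full compound name as its
#' two synonyms. Used throughout the test suite and the worked examples.
#'
#' @return An `xref_records` data frame with 10 rows spanning 5 databases.
#' @examples
#' recs <- xref_conflict_examples()
#' coll <- build_indexes(recs)
#' ids_for_name(coll, "MetaCyc", "H")
#' @export
xref_conflict_examples <- function() {
  rows <- list(
    list("MetaCyc",  "SUC",    "MNXM25",     c("suc", "succinate")),
    list("Reactome", "188980", "MNXM167",    c("suc", "sucrose")),
    list("MetaCyc",  "PROTON", "MNXM1",      c("H", "proton")),
    list("MetaCyc",  "HIS",    "MNXM134",    c("H", "L-histidine")),
    list("BiGG",     "tmp",    "MNXM87343",  c("tmp", "TMP")),
    list("ChEBI",    "10529",  "MNXM257",    c("tmp", "Thymidine monophosphate")),
    list("KEGG",     "C01081", "MNXM662",    c("tmp", "Thiamine monophosphate")),
    list("MetaCyc",  "CPD-610", "MNXM88031", c("tmp", "cyclo-triphosphoric acid")),
    list("Reactome", "1475054", "MNXM3109",  c("PPP", "triphosphate ion")),
    list("MetaCyc",  "2-PHENYL-2-1-PIPERDINYLPROPANE", "MNXM150634",
         c("PPP", "2-phenyl-2-1piperdinylpropane"))
  )
  xref_records(source_db = vapply(rows, `[[`, "", 1L),
               source_id = vapply(rows, `[[`, "", 2L),
               mnx_id = vapply(rows, `[[`, "", 3L),
               evidence = "identity",
               names = lapply(rows, `[[`, 4L))
}
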