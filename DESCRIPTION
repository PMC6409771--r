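Package: xrefaudit
Title: Namespace Consistency Audits for Metabolite Cross-Reference Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to audit the naming conventions of biochemical databases
    used in genome-scale metabolic modelling. Reads tab-separated metabolite
    cross-reference tables in the MetaNetX chem_xref dialect, builds
    bidirectional name/identifier/MNXRef association indexes, and computes
    per-database name-ambiguity and identifier-multiplicity statistics,
    pairwise inter-database mappings via shared names or via MNXRef
    identifiers, and reports of mapping inconsistencies (ambiguous
    abbreviations, cross-database name conflicts, and synonym chains joining
    distinct compounds). Includes a synthetic cross-reference generator with
    constructively known ground truth so the whole pipeline can be validated
    without downloading any database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
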