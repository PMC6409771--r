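# xrefaudit

Namespace consistency audits for metabolite cross-reference tables.

Biochemical databases used in genome-scale metabolic modelling (KEGG,
BiGG, ChEBI, MetaCyc, SEED, HMDB, ...) each keep their own namespace of
metabolite identifiers and synonyms. Translating between namespaces —
required whenever models are merged or omics data are mapped onto a model
— is only as safe as those namespaces are consistent. `xrefaudit` measures
that consistency from a MetaNetX-style `chem_xref.tsv` cross-reference
table and reports where exact-match translation goes wrong. It is aimed at
modellers deciding whether two resources can be combined automatically,
and at database curators hunting problematic synonyms.

For a database *d*, let *ids(n)* be the identifiers linked to name *n* and
*names(i)* the names linked to identifier *i*. The package computes:

* **Name ambiguity** — the distribution of |ids(n)|; a name is ambiguous
  when |ids(n)| ≥ 2. Reported as mean ± s.d., % ambiguous, and the
  maximum.
* **Identifier multiplicity** — the distribution of |names(i)| over named
  identifiers, same summaries. The two views satisfy the conservation
  identity #names · mean|ids(n)| = #named-ids · mean|names(i)| = #links,
  which is asserted on every run.
* **MNXRef-link multiplicity** — how many local identifiers each MNXRef
  reconciliation identifier gathers within a database.
* **Pairwise mapping** — for every ordered database pair, the number and
  fraction of identifiers that map into the target via byte-exact shared
  names or via shared MNXRef identifiers, and the fraction of *mapped*
  identifiers that map non-uniquely (≥ 2 targets).
* **Inconsistency findings** — ambiguous names whose identifiers carry
  different MNXRef identifiers, names meaning different compounds in
  different databases, and synonym chains (connected components of the
  identifier–name graph joining ≥ 2 distinct MNXRef identifiers), each
  with a shortest witness path.

A seeded synthetic generator (`generate_xref()`) produces cross-reference
files with planted, exactly-known structure plus an independently counted
ground truth, so the whole pipeline is testable without downloading any
database.

## Worked example

The package ships ten transcribed real cross-reference entries in which
shared abbreviations collide (`inst/extdata/conflict_examples.tsv`):

```r
library(xrefaudit)

recs <- xref_conflict_examples()          # or read_xref(<path to a chem_xref.tsv>)
coll <- build_indexes(recs)

ids_for_name(coll, "MetaCyc", "H")
#> [1] "HIS"    "PROTON"

intra_ambiguous_findings(coll$indexes$MetaCyc, coll)[[1]]
#> [intra_ambiguous] name "H": 2 member(s), 2 distinct MNXRef IDs

m <- map_by_name(coll, "MetaCyc", "Reactome")
m$entries$SUC
#> [1] "188980"
map_by_mnx(coll, "MetaCyc", "Reactome")$entries$SUC
#> character(0)
```

The name bridge happily maps MetaCyc's `SUC` (succinate, MNXM25) onto
Reactome's `188980` (sucrose, MNXM167) because both carry the
abbreviation "suc" — a mapping inconsistency. The MNXRef bridge refuses
it, since the two entries reconcile to different compounds. Summarised
over all pairs:

```r
mapping_stats(m)
#>   source_db target_db method n_source_ids n_mapped pct_mapped n_nonunique pct_nonunique_of_mapped
#> 1   MetaCyc  Reactome   name            5        2         40           0                       0
```

Two of MetaCyc's five identifiers map into Reactome by name (via "suc"
and "PPP"); both mappings join different compounds, which
`run_conflicts()` reports — on this fixture it flags exactly the
abbreviations `suc`, `H`, `tmp` and `PPP`.

## Analysis workflow

Numbered scripts under `analysis/` run the full study on a simulated
snapshot (6 databases × 200 identifiers) and write their tables under
`results/`:

```sh
Rscript analysis/01_simulate.R     # synthetic snapshot + ground truth
Rscript analysis/02_intra_audit.R  # ambiguity / multiplicity / MNXRef tables
Rscript analysis/03_inter_audit.R  # pairwise mapping matrices, both bridges
Rscript analysis/04_conflicts.R    # inconsistency findings
```

Each step states what it found and cross-checks its counts against the
generator's ground truth.

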