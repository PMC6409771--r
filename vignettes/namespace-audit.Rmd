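---
title: "Auditing metabolite namespaces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing metabolite namespaces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xrefaudit)
```

## The problem

Genome-scale metabolic models (GEMs) are assembled from biochemical
databases — KEGG, BiGG, ChEBI, MetaCyc, SEED, HMDB and others — and every
database maintains its own *namespace*: its own identifiers and its own set
of names, synonyms and abbreviations for metabolites. Combining models, or
mapping omics data onto a model, requires translating identifiers between
namespaces, and two structural properties of real databases make that
translation unsafe:

* **Name ambiguity** — the same name links to two or more identifiers
  within one database. The shorthand "H", for instance, can sit in the
  synonym lists of both the proton and L-histidine.
* **Identifier multiplicity** — one identifier carries several names.
  Multiplicity is benign (it aids readability) until an ambiguous name
  enters a synonym list, at which point chained lookups can silently
  equate different compounds.

`xrefaudit` quantifies both properties per database, maps identifiers
between database pairs via exact shared names or via MNXRef bridge
identifiers, and detects the inconsistencies those mechanisms produce.
MNXRef (from MetaNetX) is a reconciliation namespace that assigns a common
identifier (`MNXM...`) to chemically equivalent entries across databases;
the package consumes cross-reference tables in the `chem_xref.tsv` dialect:
tab-separated rows of `db:local_id`, MNXRef ID, evidence, and a
`|`-separated description of names.

## Preprocessing

Three filters run before any audit, in a fixed order so that every dropped
record is blamed on exactly one rule and the report always reconciles
(`records_in = records_out + dropped`):

1. **Local-ID prefix drops.** Cross-reference snapshots carry duplicate
   BiGG rows whose local identifier is prefixed `M_`; these shadow the real
   BiGG identifier and are removed. The default prefix is `M_` rather than
   a bare `M`, because a literal-`M` rule would also destroy legitimate
   identifiers such as `Mg2`; the literal variant remains available through
   `filter_config(drop_local_id_prefixes = list(bigg = "M"))`.
2. **Artificial compounds.** Records naming `biomass` are dropped. The
   match is whole-name and case-insensitive, not a substring match — a
   substring rule would remove real compounds whose synonyms merely
   mention biomass.
3. **Self-references.** Rows whose source database is the MetaNetX
   namespace itself are excluded, since the audit concerns the external
   databases.

Comment/header lines are skipped at parse time; the description column is
retained in full because it carries the names the whole analysis needs.
Names are trimmed of surrounding whitespace and otherwise compared
byte-exactly: no case folding, no punctuation normalization. This is a
deliberate methodological stance — the audit measures what *exact-match*
translation does, so `lecithin` and `Lecithin` are different names and
`"h"` does not match `"H"`. The evidence column is carried through
unchanged and never interpreted.

Two parsing edge cases have defined behaviour: a row with fewer than two
columns is a hard parse error naming the line number, while a first column
without a prefix separator is skipped with a warning and counted in the
parse report (such rows cannot be attributed to a database).

## The index and its invariants

`build_indexes()` turns records into one `namespace_index` per database:
`id_to_names`, its exact transpose `name_to_ids`, and `id_to_mnx`.
Duplicate links collapse. Identifiers with no names remain in the index —
they exist in the database and are counted in `n_ids` — but contribute no
name links; the multiplicity statistics report them separately as
`n_unnamed` and exclude them from means, so both conventions for the
identifier count are recoverable.

The transpose structure implies a conservation identity that every audit
must satisfy exactly:

```
n_names * mean_ids_per_name = n_named_ids * mean_names_per_id = n_links
```

The test suite asserts it on every fixture and every generated instance;
it is also a useful sanity check against any published table of these
statistics.

## Statistics

* `name_ambiguity()`: distinct names, mean and standard deviation of
  identifiers per name, count/percentage of names with two or more
  identifiers, and the maximum.
* `id_multiplicity()`: the same distribution from the identifier side,
  over named identifiers.
* `mnx_link_stats()`: how many distinct MNXRef identifiers link into the
  database and how often one MNXRef identifier gathers several local
  identifiers. Both shares are emitted: the percentage of *local
  identifiers* sitting in a shared group (`pct_ids_multi`, the
  presentation used in per-database summary tables) and the percentage of
  *MNXRef identifiers* that are multiply linked (`pct_mnx_multi`).
* `top_entries()`: the k highest-degree names or identifiers, ordered by
  degree descending with lexicographic tie-breaks so rankings are stable.

Standard deviations use the population form (divisor N) by default. At
database scale (10^3–10^6 entries) the population and sample forms are
indistinguishable, and the population form is exact on the tiny fixtures
the tests hand-count; `sd_type = "sample"` switches the divisor. Reported
TSVs round percentages and means to two decimals; all in-memory values are
full precision. Empty namespaces (no names, no identifiers, or no MNXRef
links) raise a classed error rather than returning silent zeros.

## Pairwise mapping

Two bridges are implemented. Via **names**, a source identifier maps to
every target identifier with which it shares at least one byte-identical
name — the union over all of its names, ambiguous names treated like any
other. Via **MNXRef**, it maps to every target identifier linked to one of
its MNXRef identifiers. Mapping results aggregate per *identifier*, not
per name: summary tables count identifiers mapped and divide by the source
database's (filtered) identifier count, and the non-uniqueness percentage
divides the count of identifiers with two or more targets by the count of
mapped identifiers — an identifier that does not map at all is not
"non-uniquely mapped".

The mapped *pair* relation is symmetric by construction (A maps to B iff B
maps to A), but the summary matrix is not: the two directions have
different denominators and different fan-outs. Both facts are tested —
symmetry exactly, on the pair sets, and asymmetry by example. Self-mapping
(a database onto itself) is supported for diagnostics but excluded from
the summary matrix. An identifier carrying several MNXRef identifiers
(legal in the data model, though standard snapshots assign one) maps
through the union of them.

## Inconsistency findings

The operational definition of "two different compounds" is *disagreement
of MNXRef identifiers*. Structure-based identity (InChI, MOL) is out of
scope; the cross-reference table itself carries no structures. Three
detectors share this definition:

* **Intra-database ambiguity** (`intra_ambiguous_findings`): a name whose
  identifiers do not all carry identical MNXRef sets. When a name's
  several identifiers all share one MNXRef identifier, that is a
  deliberate merge (citrate/citric-acid style) and is *not* flagged.
* **Cross-database conflicts** (`cross_db_conflicts`): a name present in
  two databases whose reachable MNXRef unions differ as sets.
* **Synonym chains** (`synonym_chains`): connected components of the
  bipartite identifier–name graph that contain two or more distinct MNXRef
  identifiers. Within such a component, chained synonym lookups can walk
  from one compound to another (the pattern where an opaque shared synonym
  makes "water" reachable from "pyruvate"). Each finding carries a witness:
  a shortest alternating id–name–id path between two identifiers with
  differing MNXRef sets, with lexicographic tie-breaks at both the pair
  and the path level so reports are byte-stable. Witnesses longer than
  `max_path_length` elements are truncated and flagged, but the component
  is still reported. Identifiers without MNXRef links can form chain
  interior but never serve as witness endpoints.

Every emitted finding is structurally guaranteed to involve at least two
distinct MNXRef identifiers; the finding's `severity` is the count of
distinct MNXRef identifiers among its members — a pragmatic ranking
device, not a biological importance measure. Findings render
deterministically to TSV (one row per member, in the classic
Abbreviation / Database / IDs in Database / MetaNetX ID / Compound(s)
layout, plus Kind, Severity and Chain columns) or to JSON that round-trips
through `findings_from_json()`.

```{r example}
coll <- build_indexes(xref_conflict_examples())
intra_ambiguous_findings(coll$indexes$MetaCyc, coll)[[1]]
mapping_stats(map_by_name(coll, "MetaCyc", "Reactome"))
```

## The synthetic generator

Real cross-reference snapshots are versioned downloads; their exact
statistics are not reproducible offline. The generator therefore emulates
the *structure* the audit measures, with every planted feature recounted
constructively during generation:

* per-database identifier sets with a configurable names-per-identifier
  distribution (`multiplicity_weights`);
* globally collision-free base names and MNXRef identifiers, so the only
  ambiguity and the only sharing is what was planted;
* planted ambiguous names (a fraction of the base name count, each linking
  two identifiers of one database);
* MNXRef identifiers shared across database pairs (a fraction of
  identifiers per pair), driving the MNXRef-bridge mapping;
* planted cross-database conflicts (one shared name, two databases,
  distinct MNXRef identifiers) and planted three-identifier synonym
  chains, kept on reserved identifiers so each is its own component.

The ground truth is computed by direct counting over the generator's raw
link tables — plain joins and tabulations, never a call into
`build_indexes()` or the audit functions — so recovery tests compare two
independent routes. The test suite additionally checks both routes against
a third: brute-force loops over raw records with no indexing at all.

Defaults describe a snapshot of six databases with 200 identifiers each, a
mean of about two names per identifier, 5% planted ambiguous names, 10%
MNXRef sharing per pair, five conflicts and two chains — values inside the
ranges observed across public biochemical databases, where ambiguity spans
roughly 0.1–30% of names and mean multiplicity roughly 1–4.3 names per
identifier. Generation uses R's seeded RNG for placement choices only;
all bookkeeping is integer counting, so a seed reproduces files
byte-identically.

What the generator does **not** emulate: realistic name morphology (the
audit is exact-match, so lexical realism is irrelevant), heavy-tailed
degree distributions (a real database's worst name links to hundreds of
identifiers; planted ambiguity links exactly two), database-size
heterogeneity, and nameless identifiers. Passing recovery tests therefore
demonstrates correctness of the counting and mapping machinery, not
calibration against any particular public snapshot.

## Problem sizes and determinism

The shipped tests audit instances of up to 4 databases and a few dozen
identifiers each (where brute-force oracles are exact and fast), 100
seeded random instances for oracle equivalence, 20 seeded generator
settings for ground-truth recovery, and the 10-row curated conflict
examples; the analysis scripts run the 6×200 default snapshot. All
randomness flows through explicit integer seeds; reports are
byte-identical across repeated runs, which the suite asserts end to end.

## Known limitations

* Exact-match semantics means trivially related names (underscore/hyphen
  variants, case) count as different names — by design, since that is
  what exact-match translation sees, but it makes the reported overlap a
  lower bound on semantic overlap.
* MNXRef disagreement is an *upper bound* proxy for "different compounds":
  reconciliation errors in the bridge itself would be flagged as
  inconsistencies, and agreements it enforces are never questioned.
* Multi-hop mapping through a third database, reaction-level tables and
  SBML models are out of scope.
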