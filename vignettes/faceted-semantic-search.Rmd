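---
title: "Faceted semantic search over integrated genomic-file metadata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Faceted semantic search over integrated genomic-file metadata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GenoFacet)
```

## The problem

Consortia such as TCGA, ENCODE and Roadmap Epigenomics publish processed
genomic data files with rich but heterogeneous metadata: the same biological
concept is labeled `uterus` at one source, `uterus nos` at another and
`corpus uteri` at a third. A scientist who wants "every file from uterine
tissue" should not need to know each source's nomenclature. GenoFacet
implements the standard answer to this problem: harmonize the metadata into
a small star schema, link the values of a fixed set of attributes to
biomedical ontology terms, and let queries optionally traverse synonyms and
sub-concepts.

## The data model

The repository is a classic data mart. A central **Item** table describes
one processed data file per row, surrounded by four dimensions:

* *Biology*: `Donor` -> `Biosample` -> `Replicate`, bridged to items through
  `Replicate2Item` (an item may combine several replicates, a replicate may
  feed several items);
* *Management*: `Project` -> `CaseStudy`, bridged through `Case2Item`;
* *Technology*: `ExperimentType`, unique per (technique, feature, target)
  triple;
* *Extraction*: `Dataset` (data type, assembly, file format).

Everything the sources report that does not map onto this schema is kept as
raw `(item, key, value)` pairs, searchable by key and value. All stored
character values are normalized at load time - lower case, trimmed,
collapsed whitespace - which is what makes every search case-insensitive.
Original casing is deliberately not preserved; the interface this package
models displays values that way (`grch38`, `kidney`). Donor ages are stored
as integer days, with `yearsToDays()` converting user-facing years at 365
days per year (30 years = 10950 days).

The query engine never reads the entity tables directly: the constructor
materializes a **denormalized view** with one row per
(item x replicate-chain x case-chain) path. An item with R replicates and C
case studies contributes R x C rows; an item missing either chain - the
normal situation for genome-annotation items, which have no biological
dimension - is null-padded so it stays searchable. Rebuilding the view on
every repository change keeps it trivially consistent; at the desk scales
this package targets (tens of thousands of items) rematerialization takes
well under a second, so no incremental maintenance is attempted.

## The knowledge base and the three matching levels

Ten attributes are *semantically enriched*: tissue, cell, disease, species,
ethnicity, technique, feature, target, platform and content type. A curated
annotation map links their raw values to terms of a multi-ontology
vocabulary (Uberon, EFO/CL, NCIT, OBI, OGG, NCBITaxon, SO fragments); each
term carries a preferred label, synonyms, cross-references and is_a /
part_of edges to other terms.

Search runs at one of three levels:

* **original** - exact equality on the normalized raw value;
* **synonym** - additionally, items whose value is annotated to any term
  whose preferred label *or synonym* equals the query;
* **expanded** - additionally, items annotated to any *descendant* of those
  terms within a bounded number of is_a/part_of hops.

For expansion the package materializes an unfolded closure of the
relationship edges: all (ancestor, descendant) pairs within `maxDepth` hops,
with the minimal hop count. The default depth is 3 ontology levels,
configurable per knowledge base; is_a and part_of are traversed
interchangeably (real deduction chains mix them, e.g. pons IS_A regional
part of brain PART_OF brain), and the per-edge type is kept only so
explanations can print it. The closure is rebuilt by the constructor; cycles
are rejected with an error naming one offending cycle, since ontology
fragments must be DAGs.

Two points of the expansion semantics were genuinely open and are fixed here
as follows:

* **Descendants only.** The interface wording "adds hypernyms and hyponyms"
  could suggest matching items annotated to *ancestors* too, but the
  published counts contradict that: an expanded search for a leaf concept
  (e.g. `endometrium`) returns exactly its synonym-level items, not the
  thousands of items of its ancestor `uterus`. We therefore read "adding
  hypernyms" as enriching the vocabulary a user can browse, not the item
  match, and expand downward only.
* **Raw substring containment at keyword level 2.** Keyword search over core
  attributes uses substring matching (`brain` matches `smooth muscle cell of
  the brain vasculature`), not token or stem matching: `cervical` must not
  match `cervix`, since the published vocabulary keeps them as distinct
  labels related only through the ontology. Whether matching should stop at
  word boundaries is unknowable from the published behavior; raw substring
  was chosen as the simpler and more inclusive reading.

## Queries, sessions, facets

A `FacetedQuery` maps attributes to selected values: values of one attribute
are alternatives (disjunction), attributes combine conjunctively. The
sentinel `ND` selects items whose attribute is null; because no ontology
concept annotates a missing value it always matches at original semantics,
and combining it with concrete values for the same attribute at
synonym/expanded level is rejected as an error rather than silently narrowed.

A `QuerySession` is an ordered list of steps - faceted queries and key-value
steps - evaluated as an intersection, so steps can be added and rolled back
in any order. Within a key-value step, predicates are OR-ed; conjunctions of
raw-metadata conditions (e.g. triple-negative receptor status) are expressed
as separate steps.

Facet counts (the numbers beside drop-down values) are distinct-item counts
computed under the query restricted to all *other* attributes
(self-exclusion). This matches the observable behavior of the modeled
interface, where selecting one data type leaves the counts of the other data
types visible and non-zero, and it makes the counts actionable: the count
promised for value v equals the cardinality of the result after selecting v.
Counts are recomputed from the denormalized view on every mutation; no
caching layer exists by design.

Deduplication is global set semantics everywhere: an item reachable through
two replicates, three case studies or several deduction chains counts once.
The published per-level count tables only add up under this convention.

## Keyword search and deduction chains

`keywordSearch()` implements four cumulative inference levels: raw key-value
pairs (1), core attribute values (2), synonym-annotated values (3) and
values annotated to bounded descendants (4). Every match is justified by a
`DeductionChain` - item, FK hops, the attribute or raw pair containing the
match, and at levels 3-4 the annotating term plus the relationship hops up
to the term the keyword resolved to. `explainItem()` returns exactly the
chains that put an item into the result, so "matched" and "explainable" are
provably equivalent (this is property-tested). When several shortest
relationship paths tie, the chain reports the lexicographically smallest by
intermediate term codes, so output is deterministic.

## Numerical and interface choices

* Page size for tabular rendering is capped at 1000 rows.
* The aggregated table view pipe-joins *sorted distinct* values, so
  aggregation is order-independent.
* Per-source/per-dataset summaries must partition the result; an item linked
  through several case studies to several sources keeps its
  lexicographically first source (fixtures and the modeled examples have one
  source per item, so this tie-break is invisible there).
* JSON query documents accept and emit strict JSON only; the level string
  must be one of `original`, `synonym`, `expanded` (the one published
  payload with a garbled level string is treated as a typo, not a dialect).
* The REST surface is provided as pure request/response functions
  (`fieldCounts()`, `fieldCountsJSON()`, exports) plus a thin Rscript CLI;
  responses are pure functions of (repository, knowledge base, payload) and
  byte-stable across calls.

## What the fixture generators emulate - and what they do not

`buildWorkedExample()` rebuilds six published counting examples from their
printed group sizes (uterus area: 16851 items over eight raw labels; k562:
5942+44; boris: 10; eye: 13+1440+20; brain: six core groups and four
raw-pair groups; prostate: 3543+1278). Each fixture item gets its own
donor/biosample/replicate/case chain and a unique synthetic source id, so
every printed count is unambiguous; groups are generated disjoint, which the
published deduction-chain table does not strictly promise for production
data, where an item may match several chains. Term codes follow the
publication where printed; the two codes never printed (eye, photoreceptor
array) use a reserved `TEST` namespace and are documented as synthetic.

`randomRepository()` generates seeded random repositories: a random DAG
ontology (parents always have smaller ids, so acyclicity is structural), a
configurable annotation rate, items with 0-2 replicates and 0-2 case studies
(so padding and combined items occur), and random raw pairs. For a sample of
(attribute, value, level) probes it records the exact answer computed by an
independent brute-force pass over the entity tables - no joins, no
materialized closure - at generation time; the test suite replays those
probes against the engine across 100+ seeds (repositories of 25-150 items;
one-off checks run into the thousands, comfortably inside a test budget of a
few minutes) and checks the query, facet, session and key-value paths
against scan oracles.

What passing these tests does **not** show about real data: the generators
produce clean, referentially intact tables with single-token value pools;
they do not emulate the vocabulary breadth, missing-data patterns,
inconsistent casing or multi-ontology ambiguity of real TCGA/ENCODE dumps,
nor source-specific download/cleaning (out of scope here - curated tables
are the input contract). Validation robustness is instead tested by seeded
corruption injection, where each injected defect (duplicate source ids,
dangling foreign keys, negative ages, illegal tri-state values) must surface
as exactly one violation.

## Known limitations

* No ranking, fuzzy matching or stemming: matching is equality/containment
  on normalized strings by design.
* Cross-ontology references are stored and exported but never used in
  matching, mirroring the modeled system.
* Expansion depth is a single bound per knowledge base; bounding hypernym
  and hyponym traversal independently would be a straightforward extension
  but nothing in the published behavior requires it.
* The backing store is in-memory data frames behind an S4 facade; the
  logical schema, not the storage engine, is the contract, and desk-scale
  collections (10^4-10^5 denormalized rows) are the intended regime.

## A worked session

```{r example}
ex <- buildWorkedExample("uterus")
repo <- ex$repository
kb <- ex$knowledgeBase

length(matchItems(repo, kb, "tissue", "uterus", "original"))
length(matchItems(repo, kb, "tissue", "uterus", "synonym"))
length(matchItems(repo, kb, "tissue", "uterus", "expanded"))

facetCounts(repo, kb, FacetedQuery(), "original", "tissue")

brain <- buildWorkedExample("brain")
pons <- subset(denormalizedView(brain$repository), tissue == "pons")$item_id[1]
chainSignature(
  explainItem(brain$repository, brain$knowledgeBase, pons, "brain", 4)[[1]])
```
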