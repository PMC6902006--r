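# GenoFacet

Faceted, ontology-aware semantic search over integrated metadata of
processed genomic data files.

## What it is for

Large consortia (TCGA, ENCODE, Roadmap Epigenomics, GENCODE, RefSeq) publish
open genomic data files whose metadata are structured differently at every
source: one source's `uterus` is another's `uterus nos` and a third's
`corpus uteri`. GenoFacet is an R implementation of the standard remedy — a
metadata *data mart* plus a multi-ontology *knowledge base* plus a query
engine — for bioinformaticians who need to locate files across sources
without knowing each source's nomenclature.

It provides:

* a **star-schema repository** (`MetadataRepository`): a central Item table
  (one processed file per row) with Biology (Donor/Biosample/Replicate),
  Management (Project/CaseStudy), Technology (ExperimentType) and Extraction
  (Dataset) dimensions, many-to-many bridges, raw `(item, key, value)` pairs
  for everything that does not fit the schema, content-consistency
  validation, and a materialized denormalized view with one row per
  (item × replicate-chain × case-chain) path;
* a **knowledge base** (`KnowledgeBase`): ontology terms with synonyms,
  cross-references, is_a/part_of edges, a curated map linking the values of
  ten enriched attributes (tissue, cell, disease, species, ethnicity,
  technique, feature, target, platform, content type) to terms, and a
  depth-bounded unfolded closure of the relationship edges (default 3
  levels);
* a **query engine**: faceted search at three semantic levels —

  | level | an item matches the query value v when … |
  |---|---|
  | `original` | its normalized raw value equals v |
  | `synonym`  | … or its value is annotated to a term whose preferred label or synonym equals v |
  | `expanded` | … or its value is annotated to a *descendant* of such a term within the depth bound |

  plus dynamic facet counts with self-exclusion, the `N/D` null sentinel,
  key/value search over raw metadata, conjunctive query sessions, per-source
  and per-dataset result summaries, replicated/aggregated result tables,
  keyword search at four inference levels, and **deduction chains** that
  explain every match as the database path from the item to the matched
  text (`<Item> - <Replicate> - <Biosample.tissue: pons> -
  <Vocabulary: pons, …> -[IS_A]- … -[PART_OF]- <Vocabulary: brain, …>`);
* **interchange**: JSON query documents (parse/serialize/round-trip), TSV
  table dumps with manifests, an OBO flat-file reader, REST-style
  field-count responses (`fieldCountsJSON()`), link and CSV exports, ten
  shipped example queries (`inst/extdata/queries/`) and a thin CLI
  (`exec/genofacet.R`);
* **fixtures**: `buildWorkedExample()` rebuilds six published counting
  examples from their printed inputs, and `randomRepository()` generates
  seeded random repositories with brute-forced ground truth for testing.

## Worked example

```r
library(GenoFacet)

ex <- buildWorkedExample("uterus")   # 16851 items over 8 raw tissue labels
repo <- ex$repository; kb <- ex$knowledgeBase

length(matchItems(repo, kb, "tissue", "uterus", "original"))
#> [1] 57
length(matchItems(repo, kb, "tissue", "uterus", "synonym"))
#> [1] 1708
length(matchItems(repo, kb, "tissue", "uterus", "expanded"))
#> [1] 16851
```

At `original` level only the 57 items literally labeled `uterus` match; at
`synonym` level the 1651 `uterus nos` items annotated to the same Uberon
concept join them (57 + 1651 = 1708); at `expanded` level every item
annotated to a sub-concept of uterus (body of uterus, uterine cervix,
uterine wall, endometrium) matches — the whole fixture, 16851 items.

Facet counts show the drop-down numbers for a (here: empty) query:

```r
facetCounts(repo, kb, FacetedQuery(), "original", "tissue")
#> corpus uteri cervix uteri   uterus nos       cervix       uterus  endometrium
#>         9535         5417         1651          167           57           21
#>  endometrial     cervical
#>            2            1
```

Every keyword match is explainable. For an item whose tissue is `pons`, the
keyword `brain` only matches through the ontology:

```r
brain <- buildWorkedExample("brain")
pons <- subset(denormalizedView(brain$repository),
               tissue == "pons")$item_id[1]
chainSignature(explainItem(brain$repository, brain$knowledgeBase,
                           pons, "brain", level = 4)[[1]])
#> [1] "<Item> - <Replicate> - <Biosample.tissue: pons> -
#>      <Vocabulary: pons, UBERON_0000988> -[IS_A]-
#>      <Vocabulary: regional part of brain, UBERON_0002616> -[PART_OF]-
#>      <Vocabulary: brain, UBERON_0000955>"
```

REST-style field counts under a payload context:

```r
p <- buildWorkedExample("prostate")
payload <- '{"gcm": {"disease": ["prostate adenocarcinoma"],
             "assembly": ["grch38"]}, "type": "original", "kv": {}}'
fieldCountsJSON(p$repository, p$knowledgeBase, payload, "is_healthy")
#> {"values":[{"value":false,"count":3543},{"value":true,"count":1278}],
#>  "info":{"shown_count":2,"total_count":2,"item_count":4821}}
```

See `vignettes/faceted-semantic-search.Rmd` for the full account of the
model, the matching semantics and the design choices.

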