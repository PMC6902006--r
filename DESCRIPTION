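Package: GenoFacet
Title: Faceted Semantic Search over Integrated Genomic-File Metadata
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A star-schema repository for metadata of processed genomic data
    files (items) integrated from heterogeneous sources, together with a
    multi-ontology knowledge base (vocabulary, synonyms, is_a/part_of
    relationships and their depth-bounded unfolded closure) and a query
    engine offering three levels of semantic matching (original values,
    synonyms, hierarchical expansion), dynamic faceted counts, key-value
    search over raw source metadata, conjunctive query sessions, deduction
    chains explaining every keyword match, JSON query documents, field-count
    responses mirroring a REST contract, and result export. Includes a
    fixtures module that rebuilds worked examples from printed counts and
    generates seeded random repositories with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'repository.R'
    'validate.R'
    'denormalize.R'
    'knowledge_base.R'
    'obo.R'
    'query.R'
    'search.R'
    'keyword.R'
    'query_io.R'
    'service.R'
    'fixtures.R'
    'io.R'
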