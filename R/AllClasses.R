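# Central S4 containers. Entity tables are plain data.frames with fixed
# column sets; constructors coerce, normalize and (for the repository)
# materialize the denormalized view the query engine reads.

# --- table schemas -----------------------------------------------------------

.INT <- "integer"; .CHR <- "character"; .NUM <- "numeric"

.REPO_SCHEMA <- list(
  donors = c(donor_id = .INT, donor_source_id = .CHR, species = .CHR,
             species_tid = .INT, age = .INT, gender = .CHR,
             ethnicity = .CHR, ethnicity_tid = .INT),
  biosamples = c(biosample_id = .INT, biosample_source_id = .CHR,
                 donor_id = .INT, biosample_type = .CHR,
                 tissue = .CHR, tissue_tid = .INT,
                 cell = .CHR, cell_tid = .INT,
                 disease = .CHR, disease_tid = .INT, is_healthy = .CHR),
  replicates = c(replicate_id = .INT, replicate_source_id = .CHR,
                 biosample_id = .INT, biological_replicate_number = .INT,
                 technical_replicate_number = .INT),
  items = c(item_id = .INT, item_source_id = .CHR,
            experiment_type_id = .INT, dataset_id = .INT,
            size = .NUM, date = .CHR, checksum = .CHR,
            content_type = .CHR, content_type_tid = .INT,
            platform = .CHR, platform_tid = .INT, pipeline = .CHR,
            source_url = .CHR, local_url = .CHR, file_name = .CHR,
            source_page = .CHR),
  caseStudies = c(case_study_id = .INT, case_study_source_id = .CHR,
                  project_id = .INT, source_site = .CHR,
                  external_reference = .CHR),
  projects = c(project_id = .INT, project_name = .CHR, source = .CHR),
  experimentTypes = c(experiment_type_id = .INT,
                      technique = .CHR, technique_tid = .INT,
                      feature = .CHR, feature_tid = .INT,
                      target = .CHR, target_tid = .INT, antibody = .CHR),
  datasets = c(dataset_id = .INT, dataset_name = .CHR, data_type = .CHR,
               assembly = .CHR, file_format = .CHR, is_annotation = .CHR),
  replicateToItem = c(item_id = .INT, replicate_id = .INT),
  caseToItem = c(item_id = .INT, case_study_id = .INT),
  rawPairs = c(item_id = .INT, key = .CHR, value = .CHR)
)

.KB_SCHEMA <- list(
  vocabulary = c(tid = .INT, ontology_source = .CHR, code = .CHR,
                 pref_label = .CHR, description = .CHR, iri = .CHR),
  synonyms = c(tid = .INT, label = .CHR, syn_type = .CHR),
  references = c(tid = .INT, ext_source = .CHR, ext_code = .CHR),
  relationships = c(parent = .INT, child = .INT, rel_type = .CHR),
  annotations = c(attribute = .CHR, raw_value = .CHR, tid = .INT)
)

# columns whose values are NOT case-normalized (codes, urls, checksums)
.VERBATIM_COLUMNS <- c("code", "iri", "source_url", "local_url",
                       "source_page", "checksum", "ext_code", "rel_type",
                       "ontology_source", "ext_source")

.emptyTable <- function(schema) {
  cols <- lapply(schema, function(ty) vector(ty, 0L))
  as.data.frame(cols, stringsAsFactors = FALSE)
}

# coerce a user table to the schema: add missing nullable columns as NA,
# coerce types, normalize character values, drop extra columns
.coerceTable <- function(tab, schema, name) {
  if (is.null(tab)) return(.emptyTable(schema))
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  out <- vector("list", length(schema))
  names(out) <- names(schema)
  n <- nrow(tab)
  for (col in names(schema)) {
    ty <- schema[[col]]
    if (col %in% names(tab)) {
      v <- tab[[col]]
      v <- switch(ty,
                  integer   = as.integer(v),
                  numeric   = as.numeric(v),
                  character = {
                    v <- as.character(v)
                    if (col %in% .VERBATIM_COLUMNS) {
                      v[!is.na(v) & !nzchar(trimws(v))] <- NA_character_
                      trimws(v)
                    } else .normalizeValue(v)
                  })
    } else {
      v <- rep(switch(ty, integer = NA_integer_, numeric = NA_real_,
                      character = NA_character_), n)
    }
    out[[col]] <- v
  }
  res <- as.data.frame(out, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# --- classes -----------------------------------------------------------------

#' MetadataRepository: star-schema store of genomic-file metadata
#'
#' An S4 container holding the eight core entity tables of the genomic
#' conceptual model (Donor, Biosample, Replicate, Item, CaseStudy, Project,
#' ExperimentType, Dataset), the two many-to-many bridge tables
#' (Replicate2Item, Case2Item), the original source metadata as raw
#' (item, key, value) pairs, and a materialized denormalized view joining
#' every core attribute per (item x replicate-chain x case-chain) path.
#' The denormalized view is the only structure the query engine reads and is
#' rematerialized by the constructor, so it is always in sync with the
#' tables.
#'
#' All character values are normalized at construction (lower case, trimmed,
#' collapsed whitespace); ids and URLs keep their original form. Use
#' [validateRepository()] for a full integrity report: the constructor only
#' enforces column structure so that deliberately corrupted repositories can
#' be represented and diagnosed.
#'
#' @slot donors,biosamples,replicates,items,caseStudies,projects,experimentTypes,datasets
#'   Entity tables (data.frames) with fixed column sets.
#' @slot replicateToItem,caseToItem Bridge tables of id pairs.
#' @slot rawPairs Original metadata, columns `item_id`, `key`, `value`.
#' @slot denormalized The materialized flat view (see [denormalize()]).
#'
#' @seealso [MetadataRepository()] constructor, [denormalize()],
#'   [validateRepository()], [loadRepository()]
#' @aliases MetadataRepository-class
#' @exportClass MetadataRepository
setClass("MetadataRepository",
  representation(
    donors = "data.frame", biosamples = "data.frame",
    replicates = "data.frame", items = "data.frame",
    caseStudies = "data.frame", projects = "data.frame",
    experimentTypes = "data.frame", datasets = "data.frame",
    replicateToItem = "data.frame", caseToItem = "data.frame",
    rawPairs = "data.frame", denormalized = "data.frame"))

setValidity("MetadataRepository", function(object) {
  slotsOf <- c(donors = "donors", biosamples = "biosamples",
               replicates = "replicates", items = "items",
               caseStudies = "caseStudies", projects = "projects",
               experimentTypes = "experimentTypes", datasets = "datasets",
               replicateToItem = "replicateToItem", caseToItem = "caseToItem",
               rawPairs = "rawPairs")
  for (nm in names(slotsOf)) {
    want <- names(.REPO_SCHEMA[[nm]])
    have <- names(slot(object, nm))
    if (!all(want %in% have))
      return(sprintf("table '%s' is missing columns: %s", nm,
                     paste(setdiff(want, have), collapse = ", ")))
  }
  TRUE
})

#' KnowledgeBase: multi-ontology vocabulary with unfolded closure
#'
#' An S4 container for ontology fragments used in semantic search: the
#' vocabulary of terms (internal `tid`, source ontology acronym, code,
#' preferred label), synonym labels, cross-references to equivalent terms in
#' other ontologies, is_a/part_of relationship edges, the curated annotation
#' map linking raw attribute values of the ten enriched attributes to term
#' ids, and the materialized depth-bounded transitive closure of the
#' relationship edges (see [unfoldClosure()]). is_a and part_of edges are
#' traversed interchangeably during expansion; the per-edge type is retained
#' for deduction-chain explanations only. Cross-references are carried and
#' exported but never affect matching.
#'
#' @slot vocabulary Terms: `tid`, `ontology_source`, `code`, `pref_label`,
#'   `description`, `iri`.
#' @slot synonyms Alternative labels: `tid`, `label`, `syn_type`.
#' @slot references Cross-ontology references: `tid`, `ext_source`,
#'   `ext_code`.
#' @slot relationships Edges: `parent`, `child`, `rel_type`
#'   (`"IS_A"`/`"PART_OF"`).
#' @slot annotations Curated map: `attribute`, `raw_value`, `tid`.
#' @slot closure Unfolded pairs: `ancestor`, `descendant`, `distance`.
#' @slot maxDepth Integer bound used to materialize the closure (default 3).
#'
#' @seealso [KnowledgeBase()] constructor, [resolveLabel()],
#'   [termDescendants()], [annotateValue()], [readOBO()]
#' @aliases KnowledgeBase-class
#' @exportClass KnowledgeBase
setClass("KnowledgeBase",
  representation(
    vocabulary = "data.frame", synonyms = "data.frame",
    references = "data.frame", relationships = "data.frame",
    annotations = "data.frame", closure = "data.frame",
    maxDepth = "integer"))

setValidity("KnowledgeBase", function(object) {
  for (nm in names(.KB_SCHEMA)) {
    want <- names(.KB_SCHEMA[[nm]])
    have <- names(slot(object, nm))
    if (!all(want %in% have))
      return(sprintf("table '%s' is missing columns: %s", nm,
                     paste(setdiff(want, have), collapse = ", ")))
  }
  if (length(object@maxDepth) != 1L || is.na(object@maxDepth) ||
      object@maxDepth < 1L)
    return("maxDepth must be a single integer >= 1")
  v <- object@vocabulary
  if (nrow(v) && anyDuplicated(v$tid))
    return("vocabulary tids must be unique")
  if (nrow(v) && anyDuplicated(paste(v$ontology_source, v$code)))
    return("(ontology_source, code) must be unique in the vocabulary")
  if (nrow(v) && any(is.na(v$pref_label)))
    return("every vocabulary term needs a non-empty pref_label")
  TRUE
})

#' FacetedQuery: attribute-to-values selections
#'
#' A faceted (drop-down style) query: a named list mapping searchable
#' attribute names to non-empty character vectors of selected values. Values
#' chosen for the same attribute are alternatives (disjunction); different
#' attributes are combined in conjunction. The sentinel [ND] selects items
#' whose attribute is null. The pseudo-attributes `max_age` / `min_age`
#' take a single number of days and bound the donor age.
#'
#' @slot selections Named list of character vectors.
#' @seealso [FacetedQuery()], [evaluateQuery()], [renderSelectedQuery()]
#' @aliases FacetedQuery-class
#' @exportClass FacetedQuery
setClass("FacetedQuery", representation(selections = "list"))

setValidity("FacetedQuery", function(object) {
  sel <- object@selections
  if (length(sel)) {
    if (is.null(names(sel)) || any(!nzchar(names(sel))))
      return("selections must be a named list")
    for (a in names(sel)) {
      if (!a %in% c(.ATTRIBUTE_REGISTRY$attribute, .AGE_BOUND_ATTRIBUTES))
        return(sprintf("'%s' is not a searchable attribute", a))
      if (!length(sel[[a]]))
        return(sprintf("empty value list for attribute '%s'", a))
    }
  }
  TRUE
})

#' KeyValuePredicate: a filter over raw source metadata
#'
#' A predicate over the raw (item, key, value) pairs: an item satisfies it
#' when it carries a pair whose key matches one of the predicate's keys and
#' whose value matches one of that key's accepted values; matching is
#' case-insensitive equality when `exact` is `TRUE` and substring containment
#' otherwise. `mode` records whether the predicate was built from a key
#' search or a value search (it does not change evaluation) and `name` is the
#' user-facing label of the step in a JSON query document.
#'
#' @slot name Step label.
#' @slot mode `"key"` or `"value"`.
#' @slot exact Logical; equality vs containment matching.
#' @slot pairs Named list: key -> character vector of accepted values.
#' @seealso [KeyValuePredicate()], [evaluateKvStep()]
#' @aliases KeyValuePredicate-class
#' @exportClass KeyValuePredicate
setClass("KeyValuePredicate",
  representation(name = "character", mode = "character",
                 exact = "logical", pairs = "list"))

setValidity("KeyValuePredicate", function(object) {
  if (!object@mode %in% c("key", "value"))
    return("mode must be 'key' or 'value'")
  if (length(object@exact) != 1L || is.na(object@exact))
    return("exact must be TRUE or FALSE")
  if (!length(object@pairs) || is.null(names(object@pairs)))
    return("pairs must be a non-empty named list")
  TRUE
})

#' QuerySession: conjunctive sequence of search steps
#'
#' An ordered sequence of search steps evaluated in conjunction: each step is
#' either a [FacetedQuery] or a key-value step (a list of
#' [KeyValuePredicate]s combined in disjunction). A single semantic level
#' applies to all faceted steps. Steps can be removed in any order; the
#' result is the intersection of the per-step results and is therefore
#' order-independent.
#'
#' @slot steps List of steps.
#' @slot level One of `semanticLevels()`.
#' @seealso [QuerySession()], [evaluateSession()], [parseQuery()]
#' @aliases QuerySession-class
#' @exportClass QuerySession
setClass("QuerySession",
  representation(steps = "list", level = "character"))

setValidity("QuerySession", function(object) {
  if (!object@level %in% .SEMANTIC_LEVELS)
    return("level must be one of original/synonym/expanded")
  for (s in object@steps) {
    ok <- is(s, "FacetedQuery") ||
      (is.list(s) && length(s) &&
         all(vapply(s, is, logical(1), "KeyValuePredicate")))
    if (!ok)
      return("each step must be a FacetedQuery or a list of KeyValuePredicate")
  }
  TRUE
})

#' ResultSet: the set of items matching a query
#'
#' A deduplicated, sorted set of item ids. An item reachable through several
#' replicates, case studies or deduction chains counts once. Use
#' [summarizeResult()] for per-source and per-dataset aggregation and
#' [renderResultTable()] for tabular views.
#'
#' @slot itemIds Sorted unique integer vector.
#' @seealso [ResultSet()], [evaluateQuery()], [summarizeResult()]
#' @aliases ResultSet-class
#' @exportClass ResultSet
setClass("ResultSet", representation(itemIds = "integer"))

setValidity("ResultSet", function(object) {
  ids <- object@itemIds
  if (anyNA(ids)) return("item ids must not be NA")
  if (is.unsorted(ids, strictly = TRUE) && length(ids) > 1)
    return("item ids must be sorted and unique")
  TRUE
})

#' DeductionChain: explained path from an item to a keyword match
#'
#' The internal path linking an item to the place where a search keyword
#' matched: the item node, foreign-key hops through core entities, the
#' entity attribute (or raw key-value pair) containing the match, and - at
#' the synonym/expanded levels - the annotating vocabulary term followed by
#' the is_a/part_of hops up to the term the keyword resolved to.
#'
#' @slot nodes List of node descriptors; each is a list with a `kind`
#'   (`"ITEM"`, `"ENTITY"`, `"RAW-PAIR"`, `"ENTITY-ATTRIBUTE"`, `"TERM"`)
#'   plus kind-specific fields.
#' @slot edges Character vector (one fewer than nodes) of edge labels among
#'   `"FK"`, `"ANNOTATED-BY"`, `"IS_A"`, `"PART_OF"`.
#' @seealso [explainItem()], [chainSignature()]
#' @aliases DeductionChain-class
#' @exportClass DeductionChain
setClass("DeductionChain",
  representation(nodes = "list", edges = "character"))

setValidity("DeductionChain", function(object) {
  if (!length(object@nodes)) return("a chain needs at least one node")
  if (length(object@edges) != length(object@nodes) - 1L)
    return("edges must be one fewer than nodes")
  if (!identical(object@nodes[[1]]$kind, "ITEM"))
    return("the first hop of a deduction chain must be the item")
  bad <- setdiff(object@edges, c("FK", "ANNOTATED-BY", "IS_A", "PART_OF"))
  if (length(bad)) return(paste("unknown edge label:", bad[1]))
  TRUE
})
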