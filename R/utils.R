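#' @import methods
NULL

#' Null-value sentinel
#'
#' Sentinel string selecting items whose attribute is null (undefined at the
#' original source). It can be used as a value in a [FacetedQuery] alongside,
#' or instead of, concrete values; matching is always performed at original
#' semantics because no ontology concept annotates a missing value.
#'
#' @format A length-one character vector, `"n/d"`.
#' @export
#' @examples
#' ND
ND <- "n/d"

.SEMANTIC_LEVELS <- c("original", "synonym", "expanded")

#' Semantic matching levels
#'
#' The three levels of semantic matching, ordered from narrowest to widest:
#' `"original"` (exact match on the normalized value found at the source),
#' `"synonym"` (adds items whose value is annotated to an ontology term whose
#' preferred label or any synonym equals the query), and `"expanded"` (adds
#' items annotated to depth-bounded sub-concepts of those terms, traversing
#' is_a and part_of relationships interchangeably).
#'
#' @return Character vector of the three level names, in increasing order of
#'   inclusiveness.
#' @export
#' @examples
#' semanticLevels()
semanticLevels <- function() .SEMANTIC_LEVELS

.matchLevel <- function(level) {
  level <- tolower(as.character(level)[1])
  if (!level %in% .SEMANTIC_LEVELS)
    stop("unknown semantic level '", level, "'; use one of: ",
         paste(.SEMANTIC_LEVELS, collapse = ", "), call. = FALSE)
  level
}

# lower-case, trim, collapse internal whitespace; empty -> NA
.normalizeValue <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[[:space:]]+", " ", x)
  x[is.na(x) | !nzchar(x) | x == "na"] <- NA_character_
  x
}

#' Normalize a metadata value
#'
#' All attribute values, raw key-value pairs and ontology labels are stored in
#' a canonical form: lower case, leading/trailing whitespace removed, internal
#' whitespace collapsed to single spaces, and empty strings mapped to `NA`.
#' Query strings receive the same treatment, which is what makes every search
#' case-insensitive.
#'
#' @param x Character vector (or anything coercible to one).
#' @return Normalized character vector of the same length.
#' @export
#' @examples
#' normalizeValue(c("  GRCh38 ", "Copy  Number Segment", ""))
normalizeValue <- function(x) .normalizeValue(x)

# --- searchable-attribute registry ------------------------------------------

# Fixed order defines the rendering order of the "Selected query" string and
# the canonical column order of the denormalized view. The 10 enriched
# attributes are the only ones that may carry ontology term ids.
.ATTRIBUTE_REGISTRY <- data.frame(
  attribute = c(
    "source", "project_name", "source_site", "external_reference",
    "dataset_name", "assembly", "data_type", "file_format", "is_annotation",
    "biosample_type", "tissue", "cell", "disease", "is_healthy",
    "species", "age", "gender", "ethnicity",
    "technique", "feature", "target", "antibody",
    "platform", "pipeline", "content_type"),
  entity = c(
    "project", "project", "case_study", "case_study",
    "dataset", "dataset", "dataset", "dataset", "dataset",
    "biosample", "biosample", "biosample", "biosample", "biosample",
    "donor", "donor", "donor", "donor",
    "experiment_type", "experiment_type", "experiment_type",
    "experiment_type",
    "item", "item", "item"),
  enriched = c(
    FALSE, FALSE, FALSE, FALSE,
    FALSE, FALSE, FALSE, FALSE, FALSE,
    FALSE, TRUE, TRUE, TRUE, FALSE,
    TRUE, FALSE, FALSE, TRUE,
    TRUE, TRUE, TRUE, FALSE,
    TRUE, FALSE, TRUE),
  ontologies = c(
    "", "", "", "",
    "", "", "", "", "",
    "", "UBERON", "EFO|CL", "NCIT", "",
    "NCBITaxon", "", "", "NCIT",
    "OBI|EFO", "NCIT", "OGG", "",
    "OBI", "", "NCIT|SO"),
  stringsAsFactors = FALSE
)

# pseudo-attributes allowed in faceted queries, evaluated as numeric bounds
# on donor age (stored in days)
.AGE_BOUND_ATTRIBUTES <- c("max_age", "min_age")

#' Registry of searchable core attributes
#'
#' The fixed set of core-schema attributes exposed to faceted search, in
#' canonical display order, with the entity table each one lives in and
#' whether its values are semantically enriched (annotated with ontology term
#' ids). Exactly ten attributes are enriched: tissue, cell, disease (of the
#' biological sample), species and ethnicity (of the donor), technique,
#' feature and target (of the experiment type), platform and content_type
#' (of the item).
#'
#' @return A data.frame with columns `attribute`, `entity`, `enriched` and
#'   `ontologies` (preferred ontology acronyms, `|`-separated, for enriched
#'   attributes).
#' @export
#' @examples
#' searchableAttributes()
searchableAttributes <- function() .ATTRIBUTE_REGISTRY

.enrichedAttributes <- function()
  .ATTRIBUTE_REGISTRY$attribute[.ATTRIBUTE_REGISTRY$enriched]

.checkSearchable <- function(attribute, allowAgeBounds = TRUE) {
  ok <- attribute %in% .ATTRIBUTE_REGISTRY$attribute ||
    (allowAgeBounds && attribute %in% .AGE_BOUND_ATTRIBUTES)
  if (!ok)
    stop("'", attribute, "' is not a searchable attribute", call. = FALSE)
  invisible(attribute)
}

#' Convert an age in years to stored days
#'
#' Donor ages are stored as integer days; user-facing filters are commonly
#' expressed in years and convert at 365 days per year (30 years = 10950
#' days).
#'
#' @param years Numeric vector of ages in years.
#' @return Integer vector of ages in days.
#' @export
#' @examples
#' yearsToDays(30)
yearsToDays <- function(years) as.integer(round(years * 365))

# stable utility: sorted unique integer ids
.idset <- function(x) sort(unique(as.integer(x[!is.na(x)])))

`%||%` <- function(a, b) if (is.null(a)) b else a
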