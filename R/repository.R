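#' Construct a metadata repository
#'
#' Builds a [MetadataRepository-class] from entity, bridge and raw-pair
#' tables. Missing nullable columns are added as `NA`, character values are
#' normalized (lower case, trimmed, collapsed whitespace) and the
#' denormalized search view is materialized. Structural requirements
#' (columns, types) are enforced here; semantic integrity (unique source ids,
#' resolvable foreign keys, legal tri-state values) is reported by
#' [validateRepository()] so that broken inputs can be loaded and diagnosed
#' rather than rejected outright.
#'
#' @param donors,biosamples,replicates,items,caseStudies,projects,experimentTypes,datasets
#'   Entity tables (data.frames or NULL for empty). See
#'   [MetadataRepository-class] for the column sets.
#' @param replicateToItem,caseToItem Bridge tables with columns
#'   `item_id`/`replicate_id` and `item_id`/`case_study_id`.
#' @param rawPairs Original metadata with columns `item_id`, `key`, `value`.
#' @return A [MetadataRepository-class] object.
#' @export
#' @examples
#' repo <- MetadataRepository()   # empty repository
#' itemCount(repo)
MetadataRepository <- function(donors = NULL, biosamples = NULL,
                               replicates = NULL, items = NULL,
                               caseStudies = NULL, projects = NULL,
                               experimentTypes = NULL, datasets = NULL,
                               replicateToItem = NULL, caseToItem = NULL,
                               rawPairs = NULL) {
  tabs <- list(donors = donors, biosamples = biosamples,
               replicates = replicates, items = items,
               caseStudies = caseStudies, projects = projects,
               experimentTypes = experimentTypes, datasets = datasets,
               replicateToItem = replicateToItem, caseToItem = caseToItem,
               rawPairs = rawPairs)
  for (nm in names(tabs))
    tabs[[nm]] <- .coerceTable(tabs[[nm]], .REPO_SCHEMA[[nm]], nm)
  obj <- new("MetadataRepository",
             donors = tabs$donors, biosamples = tabs$biosamples,
             replicates = tabs$replicates, items = tabs$items,
             caseStudies = tabs$caseStudies, projects = tabs$projects,
             experimentTypes = tabs$experimentTypes, datasets = tabs$datasets,
             replicateToItem = tabs$replicateToItem,
             caseToItem = tabs$caseToItem, rawPairs = tabs$rawPairs,
             denormalized = data.frame())
  obj@denormalized <- denormalize(obj)
  obj
}

#' Repository table accessors
#'
#' Accessors for the tables of a [MetadataRepository-class]: the eight entity
#' tables, the two bridge tables, the raw key-value pairs, the materialized
#' denormalized view and the number of items.
#'
#' @param x A `MetadataRepository`.
#' @return A data.frame (or, for `itemCount`, an integer).
#' @name repository-accessors
#' @examples
#' repo <- buildWorkedExample("boris")$repository
#' itemCount(repo)
#' head(items(repo))
NULL

#' @rdname repository-accessors
setMethod("donors", "MetadataRepository", function(x) x@donors)
#' @rdname repository-accessors
setMethod("biosamples", "MetadataRepository", function(x) x@biosamples)
#' @rdname repository-accessors
setMethod("replicates", "MetadataRepository", function(x) x@replicates)
#' @rdname repository-accessors
setMethod("items", "MetadataRepository", function(x) x@items)
#' @rdname repository-accessors
setMethod("caseStudies", "MetadataRepository", function(x) x@caseStudies)
#' @rdname repository-accessors
setMethod("projects", "MetadataRepository", function(x) x@projects)
#' @rdname repository-accessors
setMethod("experimentTypes", "MetadataRepository",
          function(x) x@experimentTypes)
#' @rdname repository-accessors
setMethod("datasets", "MetadataRepository", function(x) x@datasets)
#' @rdname repository-accessors
setMethod("replicateToItem", "MetadataRepository",
          function(x) x@replicateToItem)
#' @rdname repository-accessors
setMethod("caseToItem", "MetadataRepository", function(x) x@caseToItem)
#' @rdname repository-accessors
setMethod("rawPairs", "MetadataRepository", function(x) x@rawPairs)
#' @rdname repository-accessors
setMethod("denormalizedView", "MetadataRepository",
          function(x) x@denormalized)
#' @rdname repository-accessors
setMethod("itemCount", "MetadataRepository", function(x) nrow(x@items))

setMethod("show", "MetadataRepository", function(object) {
  cat("MetadataRepository\n")
  cat(sprintf("  items: %d  (denormalized paths: %d)\n",
              nrow(object@items), nrow(object@denormalized)))
  cat(sprintf("  donors: %d  biosamples: %d  replicates: %d\n",
              nrow(object@donors), nrow(object@biosamples),
              nrow(object@replicates)))
  cat(sprintf("  case studies: %d  projects: %d  experiment types: %d  datasets: %d\n",
              nrow(object@caseStudies), nrow(object@projects),
              nrow(object@experimentTypes), nrow(object@datasets)))
  cat(sprintf("  raw key-value pairs: %d\n", nrow(object@rawPairs)))
  invisible(NULL)
})

#' Construct a result set
#'
#' @param itemIds Integer vector of item ids; deduplicated and sorted.
#' @return A [ResultSet-class].
#' @rdname ResultSet
#' @export
#' @examples
#' r <- ResultSet(c(3L, 1L, 3L))
#' itemIds(r)
#' length(r)
ResultSet <- function(itemIds = integer(0))
  new("ResultSet", itemIds = .idset(itemIds))

#' @rdname ResultSet
#' @param x A `ResultSet`.
setMethod("itemIds", "ResultSet", function(x) x@itemIds)

#' @rdname ResultSet
#' @export
setMethod("length", "ResultSet", function(x) length(x@itemIds))

setMethod("show", "ResultSet", function(object) {
  cat(sprintf("ResultSet of %d item(s)\n", length(object@itemIds)))
  if (length(object@itemIds))
    cat("  ids:", paste(utils::head(object@itemIds, 8), collapse = ", "),
        if (length(object@itemIds) > 8) "..." else "", "\n")
  invisible(NULL)
})

.intersectResults <- function(a, b) ResultSet(intersect(itemIds(a), itemIds(b)))
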