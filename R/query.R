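#' Construct a faceted query
#'
#' @param ... Named character vectors: one argument per searchable attribute,
#'   holding the selected values ([ND] selects nulls). Alternatively a single
#'   named list.
#' @return A [FacetedQuery-class].
#' @export
#' @examples
#' q <- FacetedQuery(assembly = "grch38",
#'                   data_type = c("copy number segment",
#'                                 "masked copy number segment"),
#'                   tissue = "kidney")
#' renderSelectedQuery(q)
FacetedQuery <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && is.list(args[[1]]))
    args <- args[[1]]
  sel <- lapply(args, function(v) .normalizeValue(as.character(v)))
  if (!length(sel)) sel <- stats::setNames(list(), character(0))
  new("FacetedQuery", selections = sel)
}

#' Selections of a faceted query
#'
#' @param q A [FacetedQuery-class].
#' @return Named list of normalized value vectors.
#' @export
querySelections <- function(q) q@selections

# query with one attribute's selections removed (used by facet self-exclusion)
.dropAttribute <- function(q, attribute) {
  sel <- q@selections
  sel[[attribute]] <- NULL
  new("FacetedQuery", selections = sel)
}

setMethod("show", "FacetedQuery", function(object) {
  if (!length(object@selections)) {
    cat("FacetedQuery (empty: matches all items)\n")
  } else {
    cat("FacetedQuery\n ", renderSelectedQuery(object), "\n")
  }
  invisible(NULL)
})

#' Construct a key-value predicate
#'
#' @param pairs Named list mapping a metadata key to the character vector of
#'   its accepted values.
#' @param exact Match values by equality (`TRUE`) or substring containment
#'   (`FALSE`, the default); always case-insensitive.
#' @param mode How the predicate was discovered: `"key"` or `"value"` search.
#' @param name Label of the step (used in JSON query documents).
#' @return A [KeyValuePredicate-class].
#' @export
#' @examples
#' p <- KeyValuePredicate(pairs = list(manually_curated__fdr_threshold = "0.01"))
KeyValuePredicate <- function(pairs, exact = FALSE, mode = "key",
                              name = "kv") {
  pairs <- lapply(pairs, function(v) .normalizeValue(as.character(v)))
  names(pairs) <- .normalizeValue(names(pairs))
  new("KeyValuePredicate", name = as.character(name),
      mode = tolower(mode), exact = isTRUE(exact), pairs = pairs)
}

setMethod("show", "KeyValuePredicate", function(object) {
  cat(sprintf("KeyValuePredicate '%s' (%s, %s)\n", object@name, object@mode,
              if (object@exact) "exact" else "contains"))
  for (k in names(object@pairs))
    cat(sprintf("  %s: [%s]\n", k, paste(object@pairs[[k]], collapse = ", ")))
  invisible(NULL)
})

#' Construct a query session
#'
#' @param steps List of steps: each a [FacetedQuery-class] or a list of
#'   [KeyValuePredicate-class] objects (one key-value step, predicates in
#'   disjunction). A bare `KeyValuePredicate` is wrapped into its own step.
#' @param level Semantic level applied to faceted steps.
#' @return A [QuerySession-class].
#' @export
#' @examples
#' s <- QuerySession(list(FacetedQuery(tissue = "uterus")), level = "synonym")
QuerySession <- function(steps = list(), level = "original") {
  steps <- lapply(steps, function(s)
    if (is(s, "KeyValuePredicate")) list(s) else s)
  new("QuerySession", steps = steps, level = .matchLevel(level))
}

#' Steps and level of a query session
#'
#' @param s A [QuerySession-class].
#' @return `sessionSteps`: the list of steps; `sessionLevel`: the semantic
#'   level string.
#' @export
sessionSteps <- function(s) s@steps

#' @rdname sessionSteps
#' @export
sessionLevel <- function(s) s@level

#' Remove one step from a session
#'
#' Steps of a session are conjunctive and can be rolled back in any order;
#' removing a step and re-evaluating yields the result the session would
#' have produced without it.
#'
#' @param s A [QuerySession-class].
#' @param i Step index to drop.
#' @return The session without step `i`.
#' @export
removeStep <- function(s, i) {
  stopifnot(i >= 1, i <= length(s@steps))
  new("QuerySession", steps = s@steps[-i], level = s@level)
}

setMethod("show", "QuerySession", function(object) {
  cat(sprintf("QuerySession (%d step(s), level '%s')\n",
              length(object@steps), object@level))
  for (i in seq_along(object@steps)) {
    s <- object@steps[[i]]
    if (is(s, "FacetedQuery")) {
      cat(sprintf("  %d. faceted: %s\n", i,
                  if (length(s@selections)) renderSelectedQuery(s)
                  else "(all items)"))
    } else {
      cat(sprintf("  %d. key-value step with %d predicate(s)\n", i,
                  length(s)))
    }
  }
  invisible(NULL)
})
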