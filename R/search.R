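# Faceted search over the denormalized view, at three semantic levels.

#' Items matching one attribute value at a semantic level
#'
#' The elementary search operation. At `"original"` level, an item matches
#' when any of its denormalized paths carries exactly the (normalized) query
#' value for the attribute. At `"synonym"` level the result additionally
#' includes items whose value is annotated to any ontology term whose
#' preferred label or synonym equals the query ([resolveLabel()]). At
#' `"expanded"` level it further includes items annotated to any descendant
#' of those terms within the knowledge base's depth bound - descendants
#' only, not ancestors: searching a narrow concept never pulls in items of
#' its broader parents. The sentinel [ND] selects items whose attribute is
#' null, always at original semantics. Results are a set: each item counts
#' once however many paths or chains reach it.
#'
#' @param repo A [MetadataRepository-class].
#' @param kb A [KnowledgeBase-class].
#' @param attribute A searchable attribute name (see
#'   [searchableAttributes()]).
#' @param value The query value (or [ND]).
#' @param level One of `semanticLevels()`.
#' @return Sorted integer vector of matching item ids.
#' @export
#' @examples
#' ex <- buildWorkedExample("boris")
#' length(matchItems(ex$repository, ex$knowledgeBase, "target", "boris",
#'                   "synonym"))
matchItems <- function(repo, kb, attribute, value, level = "original") {
  level <- .matchLevel(level)
  .checkSearchable(attribute, allowAgeBounds = FALSE)
  den <- repo@denormalized
  col <- den[[attribute]]
  if (attribute == "age") col <- as.character(col)
  v <- .normalizeValue(value)
  if (!is.na(v) && v == ND)
    return(.idset(den$item_id[is.na(col)]))
  wanted <- v
  if (level != "original" &&
      attribute %in% .enrichedAttributes()) {
    tids <- resolveLabel(kb, v)
    if (level == "expanded" && length(tids))
      tids <- union(tids, termDescendants(kb, tids, kb@maxDepth))
    wanted <- unique(c(wanted, .annotatedValues(kb, attribute, tids)))
  }
  .idset(den$item_id[!is.na(col) & col %in% wanted])
}

#' Evaluate a faceted query
#'
#' For each attribute, the union of [matchItems()] over its selected values
#' (values are alternatives); across attributes, the intersection (all
#' conditions must hold). An empty query matches every item. The
#' pseudo-attributes `max_age`/`min_age` bound the donor age in days.
#' Combining [ND] with concrete values for the same attribute is only
#' possible at original level, since no ontology concept applies to a null.
#'
#' @param repo A [MetadataRepository-class].
#' @param kb A [KnowledgeBase-class].
#' @param query A [FacetedQuery-class].
#' @param level One of `semanticLevels()`.
#' @return A [ResultSet-class].
#' @export
#' @examples
#' ex <- buildWorkedExample("uterus")
#' length(evaluateQuery(ex$repository, ex$knowledgeBase,
#'                      FacetedQuery(tissue = "uterus"), "synonym"))
evaluateQuery <- function(repo, kb, query, level = "original") {
  level <- .matchLevel(level)
  stopifnot(is(query, "FacetedQuery"))
  den <- repo@denormalized
  ids <- .idset(repo@items$item_id)
  sel <- query@selections
  for (attr in names(sel)) {
    vals <- sel[[attr]]
    if (attr %in% .AGE_BOUND_ATTRIBUTES) {
      bound <- suppressWarnings(as.numeric(vals[1]))
      if (is.na(bound))
        stop("'", attr, "' needs a numeric bound in days", call. = FALSE)
      keep <- if (attr == "max_age") {
        !is.na(den$age) & den$age <= bound
      } else {
        !is.na(den$age) & den$age >= bound
      }
      matched <- .idset(den$item_id[keep])
    } else {
      if (level != "original" && ND %in% vals && length(vals) > 1L)
        stop("the null sentinel cannot be combined with concrete values ",
             "for attribute '", attr, "' at level '", level, "'",
             call. = FALSE)
      matched <- .idset(unlist(lapply(
        vals, function(v) matchItems(repo, kb, attr, v, level)),
        use.names = FALSE))
    }
    ids <- intersect(ids, matched)
    if (!length(ids)) break
  }
  ResultSet(ids)
}

#' Dynamic facet counts for one attribute
#'
#' Distinct-item counts per raw value of `attribute`, computed under the
#' current query restricted to all OTHER attributes (self-exclusion: the
#' attribute's own selections are ignored, so already-selected values keep
#' their counts in the drop-down). Items whose attribute is null are counted
#' under the [ND] entry. These are the numbers shown beside every drop-down
#' value, recomputed at each query mutation.
#'
#' @inheritParams evaluateQuery
#' @param attribute The attribute to count values for.
#' @return Named integer vector (names are raw values plus possibly `"n/d"`),
#'   sorted by decreasing count, ties by value.
#' @export
#' @examples
#' ex <- buildWorkedExample("uterus")
#' facetCounts(ex$repository, ex$knowledgeBase, FacetedQuery(), "original",
#'             "tissue")
facetCounts <- function(repo, kb, query, level, attribute) {
  .checkSearchable(attribute, allowAgeBounds = FALSE)
  res <- evaluateQuery(repo, kb, .dropAttribute(query, attribute), level)
  den <- repo@denormalized
  sub <- den[den$item_id %in% itemIds(res), c("item_id", attribute)]
  vals <- sub[[attribute]]
  if (attribute == "age") vals <- as.character(vals)
  vals[is.na(vals)] <- ND
  pairs <- unique(data.frame(item_id = sub$item_id, value = vals,
                             stringsAsFactors = FALSE))
  if (!nrow(pairs)) return(stats::setNames(integer(0), character(0)))
  tab <- table(pairs$value)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(-counts, names(counts))]
}

#' Evaluate a key-value search step
#'
#' An item satisfies a [KeyValuePredicate-class] when one of its raw
#' key-value pairs has a key matching one of the predicate's keys and a
#' value among that key's accepted values (equality when `exact`, substring
#' containment otherwise; always case-insensitive). Predicates within one
#' step are combined in disjunction - conjunctions are built by adding
#' separate steps to a [QuerySession-class].
#'
#' @param repo A [MetadataRepository-class].
#' @param predicates A list of [KeyValuePredicate-class] objects (or one
#'   predicate).
#' @return A [ResultSet-class].
#' @export
#' @examples
#' ex <- buildWorkedExample("boris")
#' evaluateKvStep(ex$repository,
#'                KeyValuePredicate(pairs = list(no_such_key = "x")))
evaluateKvStep <- function(repo, predicates) {
  if (is(predicates, "KeyValuePredicate")) predicates <- list(predicates)
  stopifnot(length(predicates) > 0,
            all(vapply(predicates, is, logical(1), "KeyValuePredicate")))
  ids <- unlist(lapply(predicates, function(p) .kvMatch(repo, p)),
                use.names = FALSE)
  ResultSet(ids)
}

.kvMatch <- function(repo, p) {
  rp <- repo@rawPairs
  if (!nrow(rp)) return(integer(0))
  hit <- rep(FALSE, nrow(rp))
  for (k in names(p@pairs)) {
    vals <- p@pairs[[k]]
    if (p@exact) {
      km <- !is.na(rp$key) & rp$key == k
      vm <- !is.na(rp$value) & rp$value %in% vals
    } else {
      km <- !is.na(rp$key) & grepl(k, rp$key, fixed = TRUE)
      vm <- Reduce(`|`, lapply(vals, function(v)
        !is.na(rp$value) & grepl(v, rp$value, fixed = TRUE)))
    }
    hit <- hit | (km & vm)
  }
  unique(rp$item_id[hit])
}

#' Evaluate a query session
#'
#' Intersects the results of every step (faceted steps at the session's
#' semantic level, key-value steps over the raw pairs). The result is
#' order-independent; removing a step with [removeStep()] and re-evaluating
#' rolls its condition back. A session with no steps matches all items.
#'
#' @param repo A [MetadataRepository-class].
#' @param kb A [KnowledgeBase-class].
#' @param session A [QuerySession-class].
#' @return A [ResultSet-class].
#' @export
#' @examples
#' ex <- buildWorkedExample("prostate")
#' s <- QuerySession(list(FacetedQuery(assembly = "grch38")))
#' length(evaluateSession(ex$repository, ex$knowledgeBase, s))
evaluateSession <- function(repo, kb, session) {
  stopifnot(is(session, "QuerySession"))
  res <- ResultSet(repo@items$item_id)
  for (s in session@steps) {
    stepRes <- if (is(s, "FacetedQuery")) {
      evaluateQuery(repo, kb, s, session@level)
    } else {
      evaluateKvStep(repo, s)
    }
    res <- .intersectResults(res, stepRes)
    if (!length(res)) break
  }
  res
}

# --- key / value discovery ---------------------------------------------------

.patternHit <- function(x, pattern, exact) {
  if (exact) !is.na(x) & x == pattern
  else !is.na(x) & grepl(pattern, x, fixed = TRUE)
}

#' Search metadata keys
#'
#' Finds where a string occurs as an attribute name, without requiring prior
#' knowledge of the schema: among the core searchable attributes (reporting
#' the number of distinct values and a few example values for each match)
#' and among the raw metadata keys (reporting the number of distinct values
#' per key; the values themselves are retrievable with [rawValuesForKey()]
#' for selection). Matching is case-insensitive, by equality or containment.
#'
#' @param repo A [MetadataRepository-class].
#' @param pattern Non-empty search string.
#' @param exact Equality instead of containment.
#' @param maxExamples Number of example values reported per core attribute.
#' @return A list with data.frames `core` (`attribute`, `n_values`,
#'   `examples`) and `raw` (`key`, `n_values`).
#' @export
#' @examples
#' ex <- buildWorkedExample("brain")
#' keySearch(ex$repository, "tissue")
keySearch <- function(repo, pattern, exact = FALSE, maxExamples = 5L) {
  pat <- .normalizeValue(pattern)
  stopifnot(!is.na(pat))
  den <- repo@denormalized
  coreAttrs <- .ATTRIBUTE_REGISTRY$attribute[
    .patternHit(.ATTRIBUTE_REGISTRY$attribute, pat, exact)]
  core <- do.call(rbind, lapply(coreAttrs, function(a) {
    vals <- den[[a]]
    if (a == "age") vals <- as.character(vals)
    vals <- sort(unique(vals[!is.na(vals)]))
    data.frame(attribute = a, n_values = length(vals),
               examples = paste(utils::head(vals, maxExamples),
                                collapse = "; "),
               stringsAsFactors = FALSE)
  }))
  if (is.null(core))
    core <- data.frame(attribute = character(0), n_values = integer(0),
                       examples = character(0), stringsAsFactors = FALSE)
  rp <- repo@rawPairs
  hits <- rp[.patternHit(rp$key, pat, exact), c("key", "value")]
  if (nrow(hits)) {
    uq <- unique(hits)
    tab <- table(uq$key)
    raw <- data.frame(key = names(tab), n_values = as.integer(tab),
                      stringsAsFactors = FALSE)
    raw <- raw[order(raw$key), , drop = FALSE]
    rownames(raw) <- NULL
  } else {
    raw <- data.frame(key = character(0), n_values = integer(0),
                      stringsAsFactors = FALSE)
  }
  list(core = core, raw = raw)
}

#' Distinct raw values recorded for a metadata key
#'
#' @param repo A [MetadataRepository-class].
#' @param key Raw metadata key (normalized, exact).
#' @return Sorted character vector of distinct values.
#' @export
rawValuesForKey <- function(repo, key) {
  k <- .normalizeValue(key)
  rp <- repo@rawPairs
  sort(unique(rp$value[!is.na(rp$key) & rp$key == k & !is.na(rp$value)]))
}

#' Search metadata values
#'
#' Symmetric to [keySearch()], matching on values: reports every core
#' (attribute, value) pair and every raw (key, value) pair whose value
#' matches the string, ready for selection as filters.
#'
#' @inheritParams keySearch
#' @return A list with data.frames `core` (`attribute`, `value`) and `raw`
#'   (`key`, `value`).
#' @export
#' @examples
#' ex <- buildWorkedExample("k562")
#' valueSearch(ex$repository, "leukemia")
valueSearch <- function(repo, pattern, exact = FALSE) {
  pat <- .normalizeValue(pattern)
  stopifnot(!is.na(pat))
  den <- repo@denormalized
  core <- do.call(rbind, lapply(.ATTRIBUTE_REGISTRY$attribute, function(a) {
    vals <- den[[a]]
    if (a == "age") vals <- as.character(vals)
    vals <- unique(vals[.patternHit(vals, pat, exact)])
    if (!length(vals)) return(NULL)
    data.frame(attribute = a, value = sort(vals), stringsAsFactors = FALSE)
  }))
  if (is.null(core))
    core <- data.frame(attribute = character(0), value = character(0),
                       stringsAsFactors = FALSE)
  rp <- repo@rawPairs
  hits <- unique(rp[.patternHit(rp$value, pat, exact), c("key", "value")])
  hits <- hits[order(hits$key, hits$value), , drop = FALSE]
  rownames(hits) <- NULL
  rownames(core) <- NULL
  list(core = core, raw = hits)
}

# --- result summarization and rendering --------------------------------------

#' Aggregate a result by source and by dataset
#'
#' Counts the result's items per origin data source (via the project each
#' item's case studies belong to) and per dataset name. Both aggregations
#' partition the result: each item contributes to exactly one bucket and
#' the counts sum to the result cardinality. An item without a management
#' chain counts under `"n/d"`.
#'
#' @param repo A [MetadataRepository-class].
#' @param result A [ResultSet-class].
#' @return List with named integer vectors `source` and `dataset`.
#' @export
#' @examples
#' ex <- buildWorkedExample("prostate")
#' summarizeResult(ex$repository, ResultSet(items(ex$repository)$item_id))
summarizeResult <- function(repo, result) {
  ids <- itemIds(result)
  if (!length(ids))
    return(list(source = stats::setNames(integer(0), character(0)),
                dataset = stats::setNames(integer(0), character(0))))
  den <- repo@denormalized
  sub <- den[den$item_id %in% ids, c("item_id", "source", "dataset_name")]
  one <- function(col) {
    v <- sub[[col]]
    v[is.na(v)] <- ND
    # an item linked to several case studies keeps one bucket (first sorted)
    per <- tapply(v, sub$item_id, function(x) sort(unique(x))[1])
    tab <- table(per)
    stats::setNames(as.integer(tab), names(tab))
  }
  list(source = one("source"), dataset = one("dataset_name"))
}

#' Tabular view of a result, replicated or aggregated
#'
#' `"replicated"` mode returns one row per denormalized path of the result's
#' items; `"aggregated"` mode returns one row per item, with multi-valued
#' fields concatenated by the pipe symbol `|` over sorted distinct values.
#' Rows are sorted stably by the requested keys and returned one page at a
#' time (page size capped at 1000 rows).
#'
#' @param repo A [MetadataRepository-class].
#' @param result A [ResultSet-class].
#' @param mode `"replicated"` or `"aggregated"`.
#' @param sortKeys Character vector of column names to sort by (default
#'   `item_source_id`).
#' @param columns Optional character vector selecting/ordering columns.
#' @param pageSize Rows per page, in `[1, 1000]`.
#' @param page 1-based page index.
#' @return A data.frame page of the results table.
#' @export
#' @examples
#' ex <- buildWorkedExample("boris")
#' renderResultTable(ex$repository, ResultSet(items(ex$repository)$item_id),
#'                   mode = "aggregated", pageSize = 5)
renderResultTable <- function(repo, result,
                              mode = c("replicated", "aggregated"),
                              sortKeys = "item_source_id", columns = NULL,
                              pageSize = 100L, page = 1L) {
  mode <- match.arg(mode)
  pageSize <- as.integer(pageSize)
  if (pageSize < 1L || pageSize > 1000L)
    stop("pageSize must be between 1 and 1000", call. = FALSE)
  tab <- .resultRows(repo, result, mode)
  if (!is.null(columns)) {
    missing <- setdiff(columns, names(tab))
    if (length(missing))
      stop("unknown column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    tab <- tab[, columns, drop = FALSE]
  }
  for (k in rev(sortKeys)) {
    if (!k %in% names(tab))
      stop("unknown sort key '", k, "'", call. = FALSE)
    tab <- tab[order(tab[[k]], na.last = TRUE, method = "radix"), ,
               drop = FALSE]
  }
  from <- (as.integer(page) - 1L) * pageSize + 1L
  to <- min(nrow(tab), from + pageSize - 1L)
  out <- if (from > nrow(tab)) tab[0, , drop = FALSE] else
    tab[seq(from, to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.resultRows <- function(repo, result, mode) {
  ids <- itemIds(result)
  den <- repo@denormalized
  sub <- den[den$item_id %in% ids, , drop = FALSE]
  if (mode == "replicated") {
    rownames(sub) <- NULL
    return(sub)
  }
  # aggregated: one row per item; pipe-join sorted distinct values
  cols <- setdiff(names(sub), "item_id")
  split_idx <- split(seq_len(nrow(sub)), sub$item_id)
  rows <- lapply(split_idx, function(ix) {
    vals <- lapply(cols, function(cl) {
      v <- unique(sub[[cl]][ix])
      v <- v[!is.na(v)]
      if (!length(v)) NA_character_
      else paste(sort(as.character(v)), collapse = "|")
    })
    names(vals) <- cols
    vals
  })
  out <- data.frame(item_id = as.integer(names(split_idx)),
                    stringsAsFactors = FALSE)
  for (cl in cols)
    out[[cl]] <- vapply(rows, function(r) r[[cl]], character(1),
                        USE.NAMES = FALSE)
  out <- out[order(out$item_id), c("item_id", cols), drop = FALSE]
  rownames(out) <- NULL
  out
}
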