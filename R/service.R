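# Pure request/response functions mirroring the REST contract: a JSON payload
# establishes the context (the result set) for the next request.

#' Field-count response for a payload context
#'
#' Implements the `/field/{field_name}` service: given a payload (a JSON
#' query document or a parsed [QuerySession-class]) that establishes the
#' context result set, returns the counts of the field's values within that
#' set, sorted by decreasing count with ties broken by value, plus an `info`
#' block with the number of values shown, the number of distinct values and
#' the size of the context result set. Repeated calls are byte-identical:
#' the response is a pure function of repository, knowledge base and
#' payload.
#'
#' @param repo A [MetadataRepository-class].
#' @param kb A [KnowledgeBase-class].
#' @param payload JSON text or [QuerySession-class].
#' @param fieldName A searchable attribute.
#' @param limit Maximum number of values returned (default all).
#' @return List with `values` (list of `list(value=, count=)`) and `info`
#'   (`shown_count`, `total_count`, `item_count`).
#' @export
#' @examples
#' ex <- buildWorkedExample("prostate")
#' payload <- '{"gcm": {"disease": ["prostate adenocarcinoma"],
#'              "assembly": ["grch38"]}, "type": "original", "kv": {}}'
#' fieldCounts(ex$repository, ex$knowledgeBase, payload, "is_healthy")$info
fieldCounts <- function(repo, kb, payload, fieldName, limit = NULL) {
  .checkSearchable(fieldName, allowAgeBounds = FALSE)
  session <- if (is(payload, "QuerySession")) payload else parseQuery(payload)
  ids <- itemIds(evaluateSession(repo, kb, session))
  den <- repo@denormalized
  sub <- den[den$item_id %in% ids, c("item_id", fieldName)]
  vals <- sub[[fieldName]]
  if (fieldName == "age") vals <- as.character(vals)
  keep <- !is.na(vals)
  pairs <- unique(data.frame(item_id = sub$item_id[keep],
                             value = vals[keep], stringsAsFactors = FALSE))
  counts <- stats::setNames(integer(0), character(0))
  if (nrow(pairs)) {
    tab <- table(pairs$value)
    counts <- stats::setNames(as.integer(tab), names(tab))
    counts <- counts[order(-counts, names(counts))]
  }
  shown <- if (is.null(limit)) length(counts)
    else min(length(counts), as.integer(limit))
  values <- lapply(seq_len(shown), function(i)
    list(value = .jsonValue(names(counts)[i]), count = counts[[i]]))
  list(values = values,
       info = list(shown_count = shown,
                   total_count = length(counts),
                   item_count = length(ids)))
}

# tri-state and boolean-like values travel as JSON booleans
.jsonValue <- function(v) {
  if (identical(v, "true")) TRUE
  else if (identical(v, "false")) FALSE
  else v
}

#' @rdname fieldCounts
#' @param ... Passed on to `fieldCounts`.
#' @return `fieldCountsJSON`: the response as canonical JSON text (`values`
#'   before `info`).
#' @export
fieldCountsJSON <- function(repo, kb, payload, fieldName, ...) {
  res <- fieldCounts(repo, kb, payload, fieldName, ...)
  as.character(jsonlite::toJSON(res, auto_unbox = TRUE))
}

#' Export download links for a result
#'
#' One URL per line, preferring the repository-local URL and falling back to
#' the source URL; items without either are skipped. Lines are ordered by
#' `item_source_id` so exports are deterministic.
#'
#' @param repo A [MetadataRepository-class].
#' @param result A [ResultSet-class].
#' @return Character scalar: newline-separated URLs (empty string for an
#'   empty result).
#' @export
#' @examples
#' ex <- buildWorkedExample("boris")
#' cat(exportLinks(ex$repository, ResultSet(items(ex$repository)$item_id[1])))
exportLinks <- function(repo, result) {
  it <- repo@items
  sub <- it[it$item_id %in% itemIds(result), , drop = FALSE]
  sub <- sub[order(sub$item_source_id), , drop = FALSE]
  url <- ifelse(!is.na(sub$local_url), sub$local_url, sub$source_url)
  paste(url[!is.na(url)], collapse = "\n")
}

#' Export a result table as CSV text
#'
#' Serializes the full results table ([renderResultTable()] rows, without
#' pagination) as RFC 4180 comma-separated text with a header row, suitable
#' for download. Sorting by donor groups same-patient rows adjacently.
#'
#' @param repo A [MetadataRepository-class].
#' @param result A [ResultSet-class].
#' @param mode `"replicated"` or `"aggregated"`.
#' @param sortKeys Columns to sort by (default `item_source_id`).
#' @param columns Optional column selection/order.
#' @return Character scalar of CSV text.
#' @export
#' @examples
#' ex <- buildWorkedExample("boris")
#' csv <- exportTable(ex$repository, ResultSet(items(ex$repository)$item_id))
#' read.csv(text = csv, nrows = 2)
exportTable <- function(repo, result, mode = c("replicated", "aggregated"),
                        sortKeys = "item_source_id", columns = NULL) {
  mode <- match.arg(mode)
  tab <- .resultRows(repo, result, mode)
  if (!is.null(columns)) tab <- tab[, columns, drop = FALSE]
  for (k in rev(sortKeys))
    tab <- tab[order(tab[[k]], na.last = TRUE, method = "radix"), ,
               drop = FALSE]
  con <- textConnection("out", "w", local = TRUE)
  utils::write.csv(tab, con, row.names = FALSE, na = "")
  close(con)
  paste(out, collapse = "\n")
}
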