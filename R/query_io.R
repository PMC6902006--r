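# JSON query dialect: {"gcm": {attr: [values]}, "type": level,
#  "kv": {name: {"type_query": "key"|"value", "exact": bool,
#                "query": {"gcm": {}, "pairs": {key: [values]}}}}}

.parseError <- function(path, msg)
  stop(sprintf("query parse error at %s: %s", path, msg), call. = FALSE)

#' Parse a JSON query document into a session
#'
#' The JSON dialect mirrors the downloadable query format of the search
#' interface: a `gcm` block of attribute-to-values selections (one faceted
#' step), a `type` giving the semantic level (defaults to `"original"` when
#' absent), and a `kv` block whose entries each become one key-value step
#' with a single predicate. Unknown attributes or level strings produce a
#' parse error naming the offending path. Strict JSON only.
#'
#' @param text JSON text (or a file path to a `.json` file).
#' @return A [QuerySession-class].
#' @export
#' @examples
#' s <- parseQuery('{"gcm": {"assembly": ["grch38"]}, "type": "original",
#'                  "kv": {}}')
#' sessionLevel(s)
parseQuery <- function(text) {
  if (length(text) == 1L && !grepl("{", text, fixed = TRUE) &&
      file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e) .parseError("$", conditionMessage(e)))
  level <- tolower(as.character(doc$type %||% "original"))
  if (!level %in% .SEMANTIC_LEVELS)
    .parseError("type", sprintf("unknown level '%s'", level))
  gcm <- doc$gcm %||% list()
  sel <- list()
  for (a in names(gcm)) {
    if (!a %in% c(.ATTRIBUTE_REGISTRY$attribute, .AGE_BOUND_ATTRIBUTES))
      .parseError(paste0("gcm.", a), "not a searchable attribute")
    vals <- unlist(gcm[[a]], use.names = FALSE)
    if (!length(vals))
      .parseError(paste0("gcm.", a), "empty value list")
    sel[[a]] <- as.character(vals)
  }
  steps <- list(FacetedQuery(sel))
  kv <- doc$kv %||% list()
  for (nm in names(kv)) {
    entry <- kv[[nm]]
    mode <- tolower(as.character(entry$type_query %||% "key"))
    if (!mode %in% c("key", "value"))
      .parseError(paste0("kv.", nm, ".type_query"),
                  sprintf("unknown mode '%s'", mode))
    exact <- isTRUE(entry$exact)
    pairs <- entry$query$pairs %||% list()
    if (!length(pairs))
      .parseError(paste0("kv.", nm, ".query.pairs"), "no pairs given")
    pairs <- lapply(pairs, function(v)
      as.character(unlist(v, use.names = FALSE)))
    steps[[length(steps) + 1L]] <-
      list(KeyValuePredicate(pairs = pairs, exact = exact, mode = mode,
                             name = nm))
  }
  QuerySession(steps = steps, level = level)
}

#' Serialize a session to a JSON query document
#'
#' Inverse of [parseQuery()] up to formatting: the selections of all faceted
#' steps are merged into the `gcm` block, the level becomes `type`, and each
#' key-value predicate becomes a named `kv` entry. Parsing the output yields
#' an equivalent session.
#'
#' @param session A [QuerySession-class].
#' @param pretty Pretty-print the JSON.
#' @return JSON text (character scalar).
#' @export
#' @examples
#' s <- QuerySession(list(FacetedQuery(tissue = "uterus")), "synonym")
#' cat(serializeQuery(s))
serializeQuery <- function(session, pretty = TRUE) {
  stopifnot(is(session, "QuerySession"))
  gcm <- list()
  kv <- list()
  kvIndex <- 0L
  for (s in session@steps) {
    if (is(s, "FacetedQuery")) {
      for (a in names(s@selections))
        gcm[[a]] <- unique(c(gcm[[a]], s@selections[[a]]))
    } else {
      for (p in s) {
        kvIndex <- kvIndex + 1L
        nm <- if (nzchar(p@name) && p@name != "kv") p@name
          else sprintf("kv_%d", kvIndex)
        kv[[nm]] <- list(type_query = p@mode, exact = p@exact,
                         query = list(gcm = stats::setNames(list(),
                                                            character(0)),
                                      pairs = p@pairs))
      }
    }
  }
  doc <- list(gcm = if (length(gcm)) gcm
                    else stats::setNames(list(), character(0)),
              type = session@level,
              kv = if (length(kv)) kv
                   else stats::setNames(list(), character(0)))
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = pretty,
                                null = "null"))
}

#' Render the human-readable "Selected query" string
#'
#' Formats a faceted query the way the search interface echoes it while the
#' user builds it: attributes in the fixed registry order, values
#' comma-joined in selection order, e.g.
#' `assembly: [grch38], data_type: [copy number segment, masked copy number
#' segment], tissue: [kidney]`. An empty query renders as the empty string.
#'
#' @param q A [FacetedQuery-class] (or a [QuerySession-class], whose faceted
#'   steps are merged).
#' @return Character scalar.
#' @export
#' @examples
#' renderSelectedQuery(FacetedQuery(tissue = "kidney", assembly = "grch38"))
renderSelectedQuery <- function(q) {
  if (is(q, "QuerySession")) {
    sel <- list()
    for (s in q@steps)
      if (is(s, "FacetedQuery"))
        for (a in names(s@selections))
          sel[[a]] <- unique(c(sel[[a]], s@selections[[a]]))
  } else {
    stopifnot(is(q, "FacetedQuery"))
    sel <- q@selections
  }
  if (!length(sel)) return("")
  ordering <- c(.ATTRIBUTE_REGISTRY$attribute, .AGE_BOUND_ATTRIBUTES)
  attrs <- names(sel)[order(match(names(sel), ordering))]
  paste(vapply(attrs, function(a)
    sprintf("%s: [%s]", a, paste(sel[[a]], collapse = ", ")),
    character(1)), collapse = ", ")
}
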