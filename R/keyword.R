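# Keyword search with deduction chains: the inference mechanism behind every
# match is recorded as the database path from the item to the matched text.

.node <- function(kind, ...) c(list(kind = kind), list(...))

.formatNode <- function(n) {
  switch(n$kind,
    ITEM = if (!is.null(n$attribute))
      sprintf("<Item.%s: %s>", n$attribute, n$value) else "<Item>",
    ENTITY = sprintf("<%s>", n$entity),
    `RAW-PAIR` = sprintf("<Key: %s, Value: %s>", n$key, n$value),
    `ENTITY-ATTRIBUTE` = sprintf("<%s.%s: %s>", n$entity, n$attribute,
                                 n$value),
    TERM = sprintf("<Vocabulary: %s, %s>", n$label, n$code),
    stop("unknown node kind ", n$kind))
}

#' Signature string of a deduction chain
#'
#' Human-readable rendering of a chain: nodes joined by `" - "`, with
#' is_a/part_of hops labeled as `-[IS_A]-` / `-[PART_OF]-`. Chains with the
#' same signature are grouped in [keywordSearch()] output.
#'
#' @param x A [DeductionChain-class].
#' @return Character scalar.
#' @rdname chainSignature
#' @export
#' @examples
#' ex <- buildWorkedExample("brain")
#' res <- keywordSearch(ex$repository, ex$knowledgeBase, "brain", level = 4)
#' head(names(res$chains))
setMethod("chainSignature", "DeductionChain", function(x) {
  parts <- .formatNode(x@nodes[[1]])
  for (i in seq_along(x@edges)) {
    sep <- if (x@edges[i] %in% c("IS_A", "PART_OF"))
      sprintf(" -[%s]- ", x@edges[i]) else " - "
    parts <- paste0(parts, sep, .formatNode(x@nodes[[i + 1L]]))
  }
  parts
})

setMethod("show", "DeductionChain", function(object) {
  cat("DeductionChain\n  ", chainSignature(object), "\n")
  invisible(NULL)
})

#' Nodes and edges of a deduction chain
#'
#' @param chain A [DeductionChain-class].
#' @return `chainNodes`: list of node descriptors; `chainEdges`: character
#'   vector of edge labels.
#' @export
chainNodes <- function(chain) chain@nodes

#' @rdname chainNodes
#' @export
chainEdges <- function(chain) chain@edges

# entity path (nodes + FK edges) from the item to the attribute holding a
# value, following the star schema
.attributePathNodes <- function(entity, attribute, value) {
  attrNode <- .node("ENTITY-ATTRIBUTE",
                    entity = .entityDisplay(entity),
                    attribute = attribute, value = value)
  switch(entity,
    item = list(nodes = list(.node("ITEM", attribute = attribute,
                                   value = value)),
                edges = character(0)),
    experiment_type = list(nodes = list(.node("ITEM"), attrNode),
                           edges = "FK"),
    dataset = list(nodes = list(.node("ITEM"), attrNode), edges = "FK"),
    biosample = list(nodes = list(.node("ITEM"),
                                  .node("ENTITY", entity = "Replicate"),
                                  attrNode),
                     edges = c("FK", "FK")),
    donor = list(nodes = list(.node("ITEM"),
                              .node("ENTITY", entity = "Replicate"),
                              .node("ENTITY", entity = "Biosample"),
                              attrNode),
                 edges = c("FK", "FK", "FK")),
    case_study = list(nodes = list(.node("ITEM"), attrNode), edges = "FK"),
    project = list(nodes = list(.node("ITEM"),
                                .node("ENTITY", entity = "CaseStudy"),
                                attrNode),
                   edges = c("FK", "FK")),
    stop("unknown entity ", entity))
}

.entityDisplay <- function(entity) {
  c(item = "Item", experiment_type = "ExperimentType", dataset = "Dataset",
    biosample = "Biosample", donor = "Donor", case_study = "CaseStudy",
    project = "Project")[[entity]]
}

.termNode <- function(kb, tid) {
  i <- match(tid, kb@vocabulary$tid)
  .node("TERM", tid = tid, label = kb@vocabulary$pref_label[i],
        code = kb@vocabulary$code[i])
}

# All match routes for a keyword up to `level`; each route is a list with
# nodes, edges, signature and the matching item ids. keywordSearch() and
# explainItem() share this.
.keywordRoutes <- function(repo, kb, keyword, level) {
  kw <- .normalizeValue(keyword)
  stopifnot(!is.na(kw), level %in% 1:4)
  den <- repo@denormalized
  routes <- list()
  addRoute <- function(nodes, edges, ids) {
    if (!length(ids)) return(invisible(NULL))
    ch <- new("DeductionChain", nodes = nodes, edges = edges)
    routes[[length(routes) + 1L]] <<- list(
      chain = ch, signature = chainSignature(ch), items = .idset(ids))
    invisible(NULL)
  }

  # level 1: raw key-value pairs whose key or value contains the keyword
  rp <- repo@rawPairs
  if (nrow(rp)) {
    m <- (!is.na(rp$key) & grepl(kw, rp$key, fixed = TRUE)) |
      (!is.na(rp$value) & grepl(kw, rp$value, fixed = TRUE))
    if (any(m)) {
      grp <- unique(rp[m, c("key", "value")])
      for (i in seq_len(nrow(grp))) {
        sel <- m & rp$key == grp$key[i] & rp$value == grp$value[i]
        addRoute(list(.node("ITEM"),
                      .node("RAW-PAIR", key = grp$key[i],
                            value = grp$value[i])),
                 "FK", rp$item_id[sel])
      }
    }
  }
  if (level < 2L) return(routes)

  # level 2: core attribute values containing the keyword (raw substring)
  reg <- .ATTRIBUTE_REGISTRY
  for (i in seq_len(nrow(reg))) {
    a <- reg$attribute[i]
    col <- den[[a]]
    if (a == "age") col <- as.character(col)
    hit <- !is.na(col) & grepl(kw, col, fixed = TRUE)
    if (!any(hit)) next
    for (v in unique(col[hit])) {
      p <- .attributePathNodes(reg$entity[i], a, v)
      addRoute(p$nodes, p$edges, den$item_id[!is.na(col) & col == v])
    }
  }
  if (level < 3L) return(routes)

  # level 3: values annotated to a term the keyword resolves to
  tids <- resolveLabel(kb, kw)
  ann <- kb@annotations
  if (length(tids) && nrow(ann)) {
    direct <- ann[ann$tid %in% tids, , drop = FALSE]
    for (i in seq_len(nrow(direct))) {
      a <- direct$attribute[i]
      ent <- reg$entity[match(a, reg$attribute)]
      col <- den[[a]]
      ids <- den$item_id[!is.na(col) & col == direct$raw_value[i]]
      if (!length(ids)) next
      p <- .attributePathNodes(ent, a, direct$raw_value[i])
      addRoute(c(p$nodes, list(.termNode(kb, direct$tid[i]))),
               c(p$edges, "ANNOTATED-BY"), ids)
    }
  }
  if (level < 4L) return(routes)

  # level 4: values annotated to bounded descendants, with the relationship
  # hops up to the resolved term
  if (length(tids) && nrow(ann)) {
    for (t in tids) {
      desc <- termDescendants(kb, t, kb@maxDepth)
      sub <- ann[ann$tid %in% desc, , drop = FALSE]
      for (i in seq_len(nrow(sub))) {
        a <- sub$attribute[i]
        ent <- reg$entity[match(a, reg$attribute)]
        col <- den[[a]]
        ids <- den$item_id[!is.na(col) & col == sub$raw_value[i]]
        if (!length(ids)) next
        path <- .shortestTermPath(kb, sub$tid[i], t)
        if (is.null(path)) next
        p <- .attributePathNodes(ent, a, sub$raw_value[i])
        termNodes <- lapply(path$tids, function(x) .termNode(kb, x))
        addRoute(c(p$nodes, termNodes),
                 c(p$edges, "ANNOTATED-BY", path$rels), ids)
      }
    }
  }
  routes
}

#' Keyword search with grouped deduction chains
#'
#' Searches a keyword across the repository at cumulative inference levels:
#' level 1 matches raw key-value pairs whose key or value contains the
#' keyword; level 2 adds core-schema attribute values containing it (raw
#' substring, case-insensitive); level 3 adds values annotated to an
#' ontology term whose preferred label or synonym equals the keyword; level
#' 4 adds values annotated to depth-bounded descendants of such terms.
#' Results are grouped by deduction-chain signature; an item may appear
#' under several signatures but is counted once in `items`.
#'
#' @param repo A [MetadataRepository-class].
#' @param kb A [KnowledgeBase-class].
#' @param keyword Non-empty search string.
#' @param level Integer 1-4; level k includes all matches of levels < k.
#' @return List with `chains` (named list: signature -> sorted item ids) and
#'   `items` (sorted union of all matched ids).
#' @export
#' @examples
#' ex <- buildWorkedExample("brain")
#' res <- keywordSearch(ex$repository, ex$knowledgeBase, "brain", level = 2)
#' res$chains[["<Item> - <Replicate> - <Biosample.tissue: brain>"]][1:5]
keywordSearch <- function(repo, kb, keyword, level = 4L) {
  level <- as.integer(level)
  routes <- .keywordRoutes(repo, kb, keyword, level)
  chains <- list()
  for (r in routes) {
    chains[[r$signature]] <- .idset(c(chains[[r$signature]], r$items))
  }
  list(chains = chains,
       items = .idset(unlist(lapply(routes, `[[`, "items"),
                             use.names = FALSE)))
}

#' Explain why an item matches a keyword
#'
#' Returns every deduction chain (bounded by the knowledge base's closure
#' depth) linking the item to the keyword at the given level: the empty list
#' exactly when the item is not in the [keywordSearch()] result.
#'
#' @param repo A [MetadataRepository-class].
#' @param kb A [KnowledgeBase-class].
#' @param itemId Integer id of an item in the repository.
#' @param keyword Search string.
#' @param level Inference level 1-4.
#' @return List of [DeductionChain-class] objects.
#' @export
#' @examples
#' ex <- buildWorkedExample("brain")
#' pons <- subset(denormalizedView(ex$repository), tissue == "pons")$item_id[1]
#' chains <- explainItem(ex$repository, ex$knowledgeBase, pons, "brain", 4)
#' chainSignature(chains[[1]])
explainItem <- function(repo, kb, itemId, keyword, level = 4L) {
  itemId <- as.integer(itemId)
  if (!itemId %in% repo@items$item_id)
    stop("unknown item id ", itemId, call. = FALSE)
  routes <- .keywordRoutes(repo, kb, keyword, as.integer(level))
  keep <- vapply(routes, function(r) itemId %in% r$items, logical(1))
  lapply(routes[keep], `[[`, "chain")
}
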