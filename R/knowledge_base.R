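#' Construct a knowledge base
#'
#' Builds a [KnowledgeBase-class] from vocabulary, synonym, reference,
#' relationship and annotation tables and materializes the depth-bounded
#' unfolded closure of the relationship edges (see [unfoldClosure()]).
#' Labels and annotation values are normalized like repository values;
#' ontology codes are kept verbatim. The relationship graph must be acyclic
#' (it may be a DAG: multiple parents are allowed).
#'
#' @param vocabulary Terms: `tid`, `ontology_source`, `code`, `pref_label`,
#'   optional `description`, `iri`.
#' @param synonyms Optional: `tid`, `label`, optional `syn_type`.
#' @param references Optional cross-references: `tid`, `ext_source`,
#'   `ext_code`.
#' @param relationships Optional edges: `parent`, `child`, `rel_type`
#'   (`"IS_A"` or `"PART_OF"`).
#' @param annotations Optional curated map: `attribute` (one of the ten
#'   enriched attributes), `raw_value`, `tid`.
#' @param maxDepth Integer depth bound for the closure; default 3 ontology
#'   levels.
#' @return A [KnowledgeBase-class].
#' @export
#' @examples
#' kb <- KnowledgeBase(
#'   vocabulary = data.frame(tid = 1:2, ontology_source = "UBERON",
#'                           code = c("UBERON_1", "UBERON_2"),
#'                           pref_label = c("organ", "part")),
#'   relationships = data.frame(parent = 1L, child = 2L,
#'                              rel_type = "PART_OF"))
#' termDescendants(kb, 1L)
KnowledgeBase <- function(vocabulary = NULL, synonyms = NULL,
                          references = NULL, relationships = NULL,
                          annotations = NULL, maxDepth = 3L) {
  tabs <- list(vocabulary = vocabulary, synonyms = synonyms,
               references = references, relationships = relationships,
               annotations = annotations)
  for (nm in names(tabs))
    tabs[[nm]] <- .coerceTable(tabs[[nm]], .KB_SCHEMA[[nm]], nm)
  tabs$relationships$rel_type <- toupper(tabs$relationships$rel_type)
  if (nrow(tabs$relationships) &&
      !all(tabs$relationships$rel_type %in% c("IS_A", "PART_OF")))
    stop("rel_type must be IS_A or PART_OF", call. = FALSE)
  if (nrow(tabs$annotations)) {
    bad <- setdiff(unique(tabs$annotations$attribute), .enrichedAttributes())
    if (length(bad))
      stop("annotation map refers to non-enriched attribute(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    badTid <- setdiff(tabs$annotations$tid, tabs$vocabulary$tid)
    if (length(badTid))
      stop("annotation map refers to unknown tid(s): ",
           paste(badTid, collapse = ", "), call. = FALSE)
  }
  maxDepth <- as.integer(maxDepth)
  closure <- unfoldClosure(tabs$relationships, maxDepth)
  new("KnowledgeBase", vocabulary = tabs$vocabulary,
      synonyms = tabs$synonyms, references = tabs$references,
      relationships = tabs$relationships, annotations = tabs$annotations,
      closure = closure, maxDepth = maxDepth)
}

#' Knowledge-base table accessors
#'
#' @param x A [KnowledgeBase-class].
#' @return A data.frame (for `maxDepth`, an integer).
#' @name kb-accessors
#' @examples
#' kb <- buildWorkedExample("uterus")$knowledgeBase
#' head(vocabulary(kb))
#' maxDepth(kb)
NULL

#' @rdname kb-accessors
setMethod("vocabulary", "KnowledgeBase", function(x) x@vocabulary)
#' @rdname kb-accessors
setMethod("synonyms", "KnowledgeBase", function(x) x@synonyms)
#' @rdname kb-accessors
setMethod("termReferences", "KnowledgeBase", function(x) x@references)
#' @rdname kb-accessors
setMethod("relationships", "KnowledgeBase", function(x) x@relationships)
#' @rdname kb-accessors
setMethod("annotations", "KnowledgeBase", function(x) x@annotations)
#' @rdname kb-accessors
setMethod("termClosure", "KnowledgeBase", function(x) x@closure)
#' @rdname kb-accessors
setMethod("maxDepth", "KnowledgeBase", function(x) x@maxDepth)

setMethod("show", "KnowledgeBase", function(object) {
  cat("KnowledgeBase\n")
  cat(sprintf("  terms: %d  synonyms: %d  references: %d\n",
              nrow(object@vocabulary), nrow(object@synonyms),
              nrow(object@references)))
  cat(sprintf("  relationship edges: %d  closure pairs: %d (max depth %d)\n",
              nrow(object@relationships), nrow(object@closure),
              object@maxDepth))
  cat(sprintf("  annotated (attribute, value) pairs: %d\n",
              nrow(object@annotations)))
  invisible(NULL)
})

# --- closure -----------------------------------------------------------------

.emptyClosure <- function() data.frame(ancestor = integer(0),
                                       descendant = integer(0),
                                       distance = integer(0))

# raise an error naming one cycle if the relationship graph has one
.checkAcyclic <- function(edges) {
  if (!nrow(edges)) return(invisible(NULL))
  nodes <- unique(c(edges$parent, edges$child))
  parentsOf <- split(edges$parent, edges$child)
  childrenOf <- split(edges$child, edges$parent)
  # Kahn's algorithm on the child -> parent orientation: a node can be
  # peeled once all of its children are gone.
  remaining <- stats::setNames(
    vapply(as.character(nodes),
           function(n) length(childrenOf[[n]] %||% integer(0)), integer(1)),
    nodes)
  queue <- nodes[remaining == 0L]
  seen <- 0L
  while (length(queue)) {
    n <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (p in parentsOf[[as.character(n)]] %||% integer(0)) {
      key <- as.character(p)
      remaining[key] <- remaining[key] - 1L
      if (remaining[key] == 0L) queue <- c(queue, p)
    }
  }
  if (seen == length(nodes)) return(invisible(NULL))
  # every unpeeled node keeps an unpeeled child, so following children
  # inside the residue must close a cycle
  residue <- as.integer(names(remaining)[remaining > 0L])
  path <- residue[1]
  repeat {
    kids <- childrenOf[[as.character(path[length(path)])]] %||% integer(0)
    nxt <- kids[kids %in% residue][1]
    if (nxt %in% path) {
      cyc <- c(path[which(path == nxt):length(path)], nxt)
      stop("relationship graph has a cycle: ",
           paste(cyc, collapse = " -> "), call. = FALSE)
    }
    path <- c(path, nxt)
  }
}

#' Unfold relationship edges into a depth-bounded closure
#'
#' Materializes the transitive closure of the is_a/part_of relationship
#' edges, bounded by `maxDepth` hops: a pair (ancestor, descendant) is
#' present iff a directed path of length at most `maxDepth` leads from the
#' descendant up to the ancestor, mixing is_a and part_of edges freely; the
#' recorded distance is the minimum such length. The edge graph may be a DAG
#' (multiple parents), but cycles are an error (the message names one cycle).
#'
#' @param edges data.frame with integer columns `parent`, `child` (and,
#'   optionally, `rel_type`, ignored here).
#' @param maxDepth Integer bound, at least 1.
#' @return data.frame with columns `ancestor`, `descendant`, `distance`
#'   (each distance in `[1, maxDepth]`; no self pairs).
#' @export
#' @examples
#' e <- data.frame(parent = c(1L, 2L), child = c(2L, 3L))
#' unfoldClosure(e, 3)   # includes (1, 3) at distance 2
unfoldClosure <- function(edges, maxDepth = 3L) {
  maxDepth <- as.integer(maxDepth)
  stopifnot(maxDepth >= 1L)
  if (is.null(edges) || !nrow(edges)) return(.emptyClosure())
  edges <- as.data.frame(edges)
  edges$parent <- as.integer(edges$parent)
  edges$child <- as.integer(edges$child)
  if (any(edges$parent == edges$child))
    stop("self loop in relationship edges", call. = FALSE)
  .checkAcyclic(edges)
  adj <- split(edges$parent, edges$child)      # upward adjacency
  starts <- sort(unique(c(edges$child, edges$parent)))
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    d <- starts[k]
    seen <- d
    frontier <- d
    anc <- integer(0); dist <- integer(0)
    for (depth in seq_len(maxDepth)) {
      nxt <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
      nxt <- setdiff(nxt, seen)
      if (!length(nxt)) break
      anc <- c(anc, nxt)
      dist <- c(dist, rep.int(depth, length(nxt)))
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    if (length(anc))
      out[[k]] <- data.frame(ancestor = anc, descendant = rep.int(d, length(anc)),
                             distance = dist)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(.emptyClosure())
  res <- do.call(rbind, out)
  res <- res[order(res$ancestor, res$descendant), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# --- lookups -----------------------------------------------------------------

#' Resolve a label to ontology term ids
#'
#' Returns the tids of every vocabulary term whose preferred label or any
#' synonym label equals the query label, case-insensitively and
#' whitespace-normalized. An empty integer vector means the label is unknown.
#'
#' @param kb A [KnowledgeBase-class].
#' @param label Query label.
#' @return Sorted integer vector of tids (possibly empty).
#' @export
#' @examples
#' kb <- buildWorkedExample("uterus")$knowledgeBase
#' resolveLabel(kb, "Corpus Uteri")
resolveLabel <- function(kb, label) {
  lab <- .normalizeValue(label)
  if (is.na(lab)) return(integer(0))
  hits <- c(kb@vocabulary$tid[!is.na(kb@vocabulary$pref_label) &
                                kb@vocabulary$pref_label == lab],
            kb@synonyms$tid[!is.na(kb@synonyms$label) &
                              kb@synonyms$label == lab])
  .idset(hits)
}

.checkKnownTid <- function(kb, tid) {
  if (!all(tid %in% kb@vocabulary$tid))
    stop("unknown term id: ",
         paste(setdiff(tid, kb@vocabulary$tid), collapse = ", "),
         call. = FALSE)
}

#' Bounded descendants and ancestors of a term
#'
#' All terms at closure distance at most `depth` below (`termDescendants`) or
#' above (`termAncestors`) the given terms, excluding the terms themselves.
#' `depth` may not exceed the depth bound the closure was materialized with.
#'
#' @param kb A [KnowledgeBase-class].
#' @param tid Integer vector of term ids (must exist in the vocabulary).
#' @param depth Integer hop bound, `1 <= depth <= maxDepth(kb)`.
#' @return Sorted integer vector of tids.
#' @export
#' @examples
#' kb <- buildWorkedExample("uterus")$knowledgeBase
#' uterus <- resolveLabel(kb, "uterus")
#' termDescendants(kb, uterus)
termDescendants <- function(kb, tid, depth = maxDepth(kb)) {
  depth <- as.integer(depth)
  if (depth < 1L || depth > kb@maxDepth)
    stop("depth must be between 1 and maxDepth(kb) = ", kb@maxDepth,
         call. = FALSE)
  .checkKnownTid(kb, tid)
  cl <- kb@closure
  .idset(cl$descendant[cl$ancestor %in% tid & cl$distance <= depth])
}

#' @rdname termDescendants
#' @export
termAncestors <- function(kb, tid, depth = maxDepth(kb)) {
  depth <- as.integer(depth)
  if (depth < 1L || depth > kb@maxDepth)
    stop("depth must be between 1 and maxDepth(kb) = ", kb@maxDepth,
         call. = FALSE)
  .checkKnownTid(kb, tid)
  cl <- kb@closure
  .idset(cl$ancestor[cl$descendant %in% tid & cl$distance <= depth])
}

#' Look up the curated annotation of a raw attribute value
#'
#' Returns the term id the curated annotation map assigns to a raw value of
#' an enriched attribute, applying the same normalization as stored values,
#' or `NA` when the value is unmapped (such items then match at the Original
#' level only). Asking about a non-enrichable attribute is an error.
#'
#' @param kb A [KnowledgeBase-class].
#' @param attribute One of the ten enriched attributes.
#' @param rawValue Raw value string.
#' @return Integer tid or `NA`.
#' @export
#' @examples
#' kb <- buildWorkedExample("uterus")$knowledgeBase
#' annotateValue(kb, "tissue", "Uterus NOS")
annotateValue <- function(kb, attribute, rawValue) {
  if (!attribute %in% .enrichedAttributes())
    stop("attribute '", attribute, "' is not semantically enriched",
         call. = FALSE)
  val <- .normalizeValue(rawValue)
  ann <- kb@annotations
  hit <- ann$tid[ann$attribute == attribute & !is.na(ann$raw_value) &
                   ann$raw_value == val]
  if (!length(hit)) NA_integer_ else hit[1]
}

# raw values of `attribute` annotated to any tid in `tids`
.annotatedValues <- function(kb, attribute, tids) {
  ann <- kb@annotations
  unique(ann$raw_value[ann$attribute == attribute & ann$tid %in% tids])
}

# all shortest upward paths descendant -> ... -> ancestor within maxDepth;
# returns the lexicographically smallest (by intermediate codes) as a list
# with tid sequence and per-hop rel types. Fragments are small, so plain
# depth-first enumeration is adequate.
.shortestTermPath <- function(kb, from, to) {
  edges <- kb@relationships
  adj <- split(seq_len(nrow(edges)), edges$child)
  best <- NULL
  walk <- function(node, path, rels) {
    if (length(path) - 1L > kb@maxDepth) return(invisible(NULL))
    if (node == to) {
      cand <- list(tids = path, rels = rels)
      if (is.null(best) || length(cand$tids) < length(best$tids) ||
          (length(cand$tids) == length(best$tids) &&
             .pathKey(kb, cand) < .pathKey(kb, best)))
        best <<- cand
      return(invisible(NULL))
    }
    for (ei in adj[[as.character(node)]] %||% integer(0)) {
      p <- edges$parent[ei]
      if (p %in% path) next
      walk(p, c(path, p), c(rels, edges$rel_type[ei]))
    }
    invisible(NULL)
  }
  walk(from, from, character(0))
  best
}

.pathKey <- function(kb, cand) {
  codes <- kb@vocabulary$code[match(cand$tids, kb@vocabulary$tid)]
  paste(c(codes, cand$rels), collapse = "|")
}
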