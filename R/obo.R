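# Convenience reader for OBO flat files: extracts exactly what the knowledge
# base needs (id, name, synonyms, is_a, relationship: part_of) from [Term]
# stanzas; everything else in the file is ignored.

#' Read an ontology fragment from an OBO flat file
#'
#' Parses `[Term]` stanzas of an OBO 1.2/1.4 flat file into the
#' knowledge-base tables: `id` and `name` become vocabulary rows (the
#' ontology acronym is taken from the id prefix, e.g. `UBERON` from
#' `UBERON:0000995`, and the stored code replaces `:` with `_`),
#' `synonym: "label" TYPE []` lines become synonym rows, and `is_a` /
#' `relationship: part_of` lines become relationship edges (obsolete terms
#' are skipped; edges to terms outside the file are dropped).
#'
#' @param path OBO file path.
#' @param maxDepth Closure depth bound passed to [KnowledgeBase()].
#' @param asKnowledgeBase Return a ready [KnowledgeBase-class] (default);
#'   otherwise the raw table list (`vocabulary`, `synonyms`,
#'   `relationships`).
#' @return A [KnowledgeBase-class] or a list of tables.
#' @export
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("[Term]", "id: XX:0000001", "name: organ", "",
#'              "[Term]", "id: XX:0000002", "name: organ part",
#'              "synonym: \"part of organ\" EXACT []",
#'              "relationship: part_of XX:0000001"), obo)
#' kb <- readOBO(obo)
#' resolveLabel(kb, "part of organ")
readOBO <- function(path, maxDepth = 3L, asKnowledgeBase = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s*!.*$", "", lines)           # strip trailing comments
  stanzaStarts <- grep("^\\[", lines)
  termStarts <- grep("^\\[Term\\]$", lines)
  terms <- list()
  for (s in termStarts) {
    nxt <- stanzaStarts[stanzaStarts > s]
    end <- if (length(nxt)) nxt[1] - 1L else length(lines)
    block <- lines[(s + 1L):end]
    tag <- sub(":.*$", "", block)
    val <- trimws(sub("^[^:]+:\\s*", "", block))
    if (any(tag == "is_obsolete" & val == "true")) next
    id <- val[tag == "id"][1]
    nm <- val[tag == "name"][1]
    if (is.na(id) || is.na(nm)) next
    syn <- val[tag == "synonym"]
    syn <- sub('^"(.*)".*$', "\\1", syn)
    synType <- val[tag == "synonym"]
    synType <- trimws(sub('^".*"\\s*', "", synType))
    synType <- tolower(sub("\\s*\\[.*$", "", synType))
    isa <- val[tag == "is_a"]
    po <- val[tag == "relationship"]
    po <- po[grepl("^part_of\\s", po)]
    po <- trimws(sub("^part_of\\s+", "", po))
    terms[[length(terms) + 1L]] <- list(id = id, name = nm, syn = syn,
                                        synType = synType, isa = isa,
                                        po = po)
  }
  if (!length(terms))
    stop("no [Term] stanzas found in '", path, "'", call. = FALSE)
  ids <- vapply(terms, `[[`, character(1), "id")
  tid <- seq_along(ids)
  vocabulary <- data.frame(
    tid = tid,
    ontology_source = sub(":.*$", "", ids),
    code = gsub(":", "_", ids),
    pref_label = vapply(terms, `[[`, character(1), "name"))
  synonyms <- do.call(rbind, lapply(seq_along(terms), function(k) {
    s <- terms[[k]]$syn
    if (!length(s)) return(NULL)
    data.frame(tid = tid[k], label = s,
               syn_type = ifelse(nzchar(terms[[k]]$synType),
                                 terms[[k]]$synType, NA_character_))
  }))
  edge <- function(k, parents, type) {
    p <- match(parents, ids)
    p <- p[!is.na(p)]
    if (!length(p)) return(NULL)
    data.frame(parent = p, child = tid[k], rel_type = type)
  }
  relationships <- do.call(rbind, c(
    lapply(seq_along(terms), function(k) edge(k, terms[[k]]$isa, "IS_A")),
    lapply(seq_along(terms), function(k) edge(k, terms[[k]]$po, "PART_OF"))))
  out <- list(vocabulary = vocabulary, synonyms = synonyms,
              relationships = relationships)
  if (!asKnowledgeBase) return(out)
  KnowledgeBase(vocabulary = vocabulary, synonyms = synonyms,
                relationships = relationships, maxDepth = maxDepth)
}
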