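# External interchange: one UTF-8 TSV per table with a header row, nulls as
# empty cells, plus a JSON manifest naming the table files.

.REPO_TABLES <- names(.REPO_SCHEMA)
.KB_TABLES <- names(.KB_SCHEMA)

.writeTSV <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
}

.readTSV <- function(path, schema) {
  classes <- unname(vapply(schema, identity, character(1)))
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           na.strings = "", check.names = FALSE,
                           fileEncoding = "UTF-8", comment.char = "")
  missing <- setdiff(names(schema), names(tab))
  # all schema columns are written by writeRepository; a missing mandatory
  # column in a hand-made dump is a format error
  mandatory <- grepl("_id$|^key$|^value$|^parent$|^child$|^tid$", names(schema))
  if (any(names(schema)[mandatory] %in% missing))
    stop("format error in '", basename(path), "': missing column(s) ",
         paste(intersect(names(schema)[mandatory], missing),
               collapse = ", "), call. = FALSE)
  tab
}

#' Write a repository to a directory of TSV files
#'
#' Writes one TSV per table (header row, empty cells for nulls) plus a
#' `manifest.json` naming them; [loadRepository()] reads the result back into
#' an identical repository.
#'
#' @param repo A [MetadataRepository-class].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
#' @examples
#' d <- tempfile(); ex <- buildWorkedExample("boris")
#' writeRepository(ex$repository, d)
#' list.files(d)
writeRepository <- function(repo, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (nm in .REPO_TABLES) {
    f <- paste0(nm, ".tsv")
    .writeTSV(slot(repo, nm), file.path(dir, f))
    manifest[[nm]] <- f
  }
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(mf)
}

#' Load a repository from a manifest of TSV files
#'
#' Reads the tables named by a manifest (as written by [writeRepository()];
#' either the manifest path or its directory may be given), rebuilds the
#' repository and rematerializes the denormalized view. Internal ids are kept
#' as stored, so a store/load round trip is exact. Missing mandatory columns
#' raise a format error; unresolvable foreign keys raise an integrity error
#' naming the offending rows unless `check = FALSE` (use
#' [validateRepository()] to inspect them).
#'
#' @param path Manifest file or directory containing `manifest.json`.
#' @param check Raise an error on integrity violations (default `TRUE`).
#' @return A [MetadataRepository-class].
#' @export
#' @examples
#' d <- tempfile(); ex <- buildWorkedExample("boris")
#' writeRepository(ex$repository, d)
#' itemCount(loadRepository(d))
loadRepository <- function(path, check = TRUE) {
  mf <- if (dir.exists(path)) file.path(path, "manifest.json") else path
  if (!file.exists(mf))
    stop("manifest not found at '", mf, "'", call. = FALSE)
  manifest <- jsonlite::read_json(mf)
  base <- dirname(mf)
  tabs <- list()
  for (nm in .REPO_TABLES) {
    f <- manifest[[nm]]
    tabs[[nm]] <- if (is.null(f)) NULL
      else .readTSV(file.path(base, f), .REPO_SCHEMA[[nm]])
  }
  repo <- do.call(MetadataRepository, tabs)
  if (check) {
    rep <- validateRepository(repo)
    bad <- rep[rep$rule %in% c("dangling_fk", "missing_pk"), , drop = FALSE]
    if (nrow(bad))
      stop("integrity error: ", bad$detail[1],
           if (nrow(bad) > 1) sprintf(" (and %d more)", nrow(bad) - 1),
           call. = FALSE)
  }
  repo
}

#' Write / load a knowledge base as TSV tables
#'
#' Mirrors the five knowledge-base tables (vocabulary, synonyms, references,
#' relationships, annotations) as TSVs plus a `kb_manifest.json`; the closure
#' is rematerialized on load with the stored depth bound.
#'
#' @param kb A [KnowledgeBase-class].
#' @param dir Output directory.
#' @return `writeKnowledgeBase`: the manifest path, invisibly;
#'   `loadKnowledgeBase`: a [KnowledgeBase-class].
#' @export
#' @examples
#' d <- tempfile(); ex <- buildWorkedExample("uterus")
#' writeKnowledgeBase(ex$knowledgeBase, d)
#' maxDepth(loadKnowledgeBase(d))
writeKnowledgeBase <- function(kb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(max_depth = maxDepth(kb))
  for (nm in .KB_TABLES) {
    f <- paste0(nm, ".tsv")
    .writeTSV(slot(kb, nm), file.path(dir, f))
    manifest[[nm]] <- f
  }
  mf <- file.path(dir, "kb_manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(mf)
}

#' @rdname writeKnowledgeBase
#' @param path Manifest file or its directory.
#' @param maxDepth Override the stored closure depth bound.
#' @export
loadKnowledgeBase <- function(path, maxDepth = NULL) {
  mf <- if (dir.exists(path)) file.path(path, "kb_manifest.json") else path
  if (!file.exists(mf))
    stop("knowledge-base manifest not found at '", mf, "'", call. = FALSE)
  manifest <- jsonlite::read_json(mf)
  base <- dirname(mf)
  tabs <- list()
  for (nm in .KB_TABLES) {
    f <- manifest[[nm]]
    tabs[[nm]] <- if (is.null(f)) NULL
      else .readTSV(file.path(base, f), .KB_SCHEMA[[nm]])
  }
  KnowledgeBase(vocabulary = tabs$vocabulary, synonyms = tabs$synonyms,
                references = tabs$references,
                relationships = tabs$relationships,
                annotations = tabs$annotations,
                maxDepth = maxDepth %||% manifest$max_depth %||% 3L)
}
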