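# Content-consistency check: integrity constraints and legal values are
# verified after loading; violations are returned as data, not raised.

.violation <- function(rule, table, detail) {
  data.frame(rule = rule, table = table, detail = detail,
             stringsAsFactors = FALSE)
}

.checkUnique <- function(vals, rule, table, what) {
  vals <- vals[!is.na(vals)]
  dup <- unique(vals[duplicated(vals)])
  if (!length(dup)) return(NULL)
  do.call(rbind, lapply(dup, function(d)
    .violation(rule, table, sprintf("duplicate %s '%s'", what, d))))
}

.checkFK <- function(child, childTab, col, parentIds, parentTab) {
  bad <- unique(child[!is.na(child) & !child %in% parentIds])
  if (!length(bad)) return(NULL)
  do.call(rbind, lapply(bad, function(b)
    .violation("dangling_fk", childTab,
               sprintf("%s=%s does not resolve in %s", col, b, parentTab))))
}

#' Validate a repository against its integrity constraints
#'
#' Checks every type invariant of the schema: uniqueness of secondary source
#' ids (and of `project_name`, `dataset_name` and the experiment-type triple
#' technique/feature/target), resolvability of all foreign keys including
#' bridge-table ends, uniqueness of bridge pairs and raw key-value triples,
#' non-negative donor ages, legal tri-state `is_healthy` values and - when a
#' knowledge base is supplied - resolvability of every term id carried by an
#' enriched attribute. Violations are data: the report is empty if and only
#' if the repository satisfies all invariants.
#'
#' @param repo A [MetadataRepository-class].
#' @param kb Optional [KnowledgeBase-class]; enables term-id checks.
#' @return A data.frame with columns `rule`, `table`, `detail`; zero rows for
#'   a valid repository.
#' @export
#' @examples
#' ex <- buildWorkedExample("boris")
#' nrow(validateRepository(ex$repository, ex$knowledgeBase))  # 0
validateRepository <- function(repo, kb = NULL) {
  stopifnot(is(repo, "MetadataRepository"))
  v <- list()

  v[[length(v) + 1L]] <- .checkUnique(repo@donors$donor_source_id,
    "duplicate_source_id", "donors", "donor_source_id")
  v[[length(v) + 1L]] <- .checkUnique(repo@biosamples$biosample_source_id,
    "duplicate_source_id", "biosamples", "biosample_source_id")
  v[[length(v) + 1L]] <- .checkUnique(repo@replicates$replicate_source_id,
    "duplicate_source_id", "replicates", "replicate_source_id")
  v[[length(v) + 1L]] <- .checkUnique(repo@items$item_source_id,
    "duplicate_source_id", "items", "item_source_id")
  v[[length(v) + 1L]] <- .checkUnique(repo@caseStudies$case_study_source_id,
    "duplicate_source_id", "caseStudies", "case_study_source_id")
  v[[length(v) + 1L]] <- .checkUnique(repo@projects$project_name,
    "duplicate_name", "projects", "project_name")
  v[[length(v) + 1L]] <- .checkUnique(repo@datasets$dataset_name,
    "duplicate_name", "datasets", "dataset_name")
  et <- repo@experimentTypes
  v[[length(v) + 1L]] <- .checkUnique(
    if (nrow(et)) paste(et$technique, et$feature, et$target, sep = " / ")
    else character(0),
    "duplicate_triple", "experimentTypes", "(technique, feature, target)")

  # primary keys must be unique and present
  for (spec in list(c("donors", "donor_id"), c("biosamples", "biosample_id"),
                    c("replicates", "replicate_id"), c("items", "item_id"),
                    c("caseStudies", "case_study_id"),
                    c("projects", "project_id"),
                    c("experimentTypes", "experiment_type_id"),
                    c("datasets", "dataset_id"))) {
    ids <- slot(repo, spec[1])[[spec[2]]]
    v[[length(v) + 1L]] <- .checkUnique(ids, "duplicate_pk", spec[1], spec[2])
    if (anyNA(ids))
      v[[length(v) + 1L]] <- .violation("missing_pk", spec[1],
                                        sprintf("NA in %s", spec[2]))
  }

  v[[length(v) + 1L]] <- .checkFK(repo@biosamples$donor_id, "biosamples",
    "donor_id", repo@donors$donor_id, "donors")
  v[[length(v) + 1L]] <- .checkFK(repo@replicates$biosample_id, "replicates",
    "biosample_id", repo@biosamples$biosample_id, "biosamples")
  v[[length(v) + 1L]] <- .checkFK(repo@items$experiment_type_id, "items",
    "experiment_type_id", repo@experimentTypes$experiment_type_id,
    "experimentTypes")
  v[[length(v) + 1L]] <- .checkFK(repo@items$dataset_id, "items",
    "dataset_id", repo@datasets$dataset_id, "datasets")
  v[[length(v) + 1L]] <- .checkFK(repo@caseStudies$project_id, "caseStudies",
    "project_id", repo@projects$project_id, "projects")
  v[[length(v) + 1L]] <- .checkFK(repo@replicateToItem$item_id,
    "replicateToItem", "item_id", repo@items$item_id, "items")
  v[[length(v) + 1L]] <- .checkFK(repo@replicateToItem$replicate_id,
    "replicateToItem", "replicate_id", repo@replicates$replicate_id,
    "replicates")
  v[[length(v) + 1L]] <- .checkFK(repo@caseToItem$item_id, "caseToItem",
    "item_id", repo@items$item_id, "items")
  v[[length(v) + 1L]] <- .checkFK(repo@caseToItem$case_study_id, "caseToItem",
    "case_study_id", repo@caseStudies$case_study_id, "caseStudies")
  v[[length(v) + 1L]] <- .checkFK(repo@rawPairs$item_id, "rawPairs",
    "item_id", repo@items$item_id, "items")

  r2i <- repo@replicateToItem
  if (nrow(r2i))
    v[[length(v) + 1L]] <- .checkUnique(
      paste(r2i$item_id, r2i$replicate_id), "duplicate_bridge_pair",
      "replicateToItem", "(item_id, replicate_id)")
  c2i <- repo@caseToItem
  if (nrow(c2i))
    v[[length(v) + 1L]] <- .checkUnique(
      paste(c2i$item_id, c2i$case_study_id), "duplicate_bridge_pair",
      "caseToItem", "(item_id, case_study_id)")
  rp <- repo@rawPairs
  if (nrow(rp))
    v[[length(v) + 1L]] <- .checkUnique(
      paste(rp$item_id, rp$key, rp$value, sep = "\r"), "duplicate_raw_pair",
      "rawPairs", "(item_id, key, value)")

  age <- repo@donors$age
  badAge <- which(!is.na(age) & age < 0)
  for (i in badAge)
    v[[length(v) + 1L]] <- .violation("illegal_value", "donors",
      sprintf("negative age %d for donor_id=%s", age[i],
              repo@donors$donor_id[i]))

  ih <- repo@biosamples$is_healthy
  badIh <- which(!is.na(ih) & !ih %in% c("true", "false"))
  for (i in badIh)
    v[[length(v) + 1L]] <- .violation("illegal_value", "biosamples",
      sprintf("is_healthy='%s' for biosample_id=%s (must be true/false/NA)",
              ih[i], repo@biosamples$biosample_id[i]))

  if (!is.null(kb)) {
    tids <- kb@vocabulary$tid
    reg <- .ATTRIBUTE_REGISTRY
    tabOf <- c(donor = "donors", biosample = "biosamples", item = "items",
               experiment_type = "experimentTypes")
    for (i in which(reg$enriched)) {
      tab <- tabOf[[reg$entity[i]]]
      col <- paste0(reg$attribute[i], "_tid")
      have <- slot(repo, tab)[[col]]
      bad <- unique(have[!is.na(have) & !have %in% tids])
      for (b in bad)
        v[[length(v) + 1L]] <- .violation("unknown_term_id", tab,
          sprintf("%s=%s not in knowledge base", col, b))
    }
  }

  v <- v[!vapply(v, is.null, logical(1))]
  if (!length(v))
    return(data.frame(rule = character(0), table = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}
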