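# Materialization of the flat search view: one row per
# (item x replicate-chain x case-chain) path, carrying every core attribute.

.DENORM_COLUMNS <- c(
  "item_id", "item_source_id", "size", "date", "checksum",
  "content_type", "content_type_tid", "platform", "platform_tid", "pipeline",
  "source_url", "local_url", "file_name", "source_page",
  "experiment_type_id", "technique", "technique_tid", "feature",
  "feature_tid", "target", "target_tid", "antibody",
  "dataset_id", "dataset_name", "data_type", "assembly", "file_format",
  "is_annotation",
  "replicate_id", "replicate_source_id", "biological_replicate_number",
  "technical_replicate_number",
  "biosample_id", "biosample_source_id", "biosample_type",
  "tissue", "tissue_tid", "cell", "cell_tid", "disease", "disease_tid",
  "is_healthy",
  "donor_id", "donor_source_id", "species", "species_tid", "age", "gender",
  "ethnicity", "ethnicity_tid",
  "case_study_id", "case_study_source_id", "source_site",
  "external_reference", "project_id", "project_name", "source")

#' Denormalize a repository into its flat search view
#'
#' Joins the eight core tables into one flat row per item-to-dimension path:
#' an item linked to R replicates and C case studies yields `R * C` rows
#' (with `R` or `C` treated as 1 via null padding when a bridge is empty, so
#' items without a biological or management chain - e.g. annotation items -
#' remain searchable). Every core attribute appears exactly once per row.
#' This view is recomputed from scratch by the [MetadataRepository()]
#' constructor on every repository change and is the only structure the
#' query engine reads.
#'
#' @param repo A [MetadataRepository-class].
#' @return A data.frame with one row per denormalized path, ordered by
#'   `item_id`, `replicate_id`, `case_study_id`.
#' @export
#' @examples
#' ex <- buildWorkedExample("boris")
#' nrow(denormalize(ex$repository))
denormalize <- function(repo) {
  it <- repo@items
  if (!nrow(it)) {
    out <- as.data.frame(
      stats::setNames(rep(list(logical(0)), length(.DENORM_COLUMNS)),
                      .DENORM_COLUMNS))
    return(out)
  }
  ids <- data.frame(item_id = it$item_id)

  # biological chain: item -> replicate -> biosample -> donor (null-padded)
  bio <- merge(ids, repo@replicateToItem, by = "item_id", all.x = TRUE)
  bio <- merge(bio, repo@replicates, by = "replicate_id", all.x = TRUE)
  bio <- merge(bio, repo@biosamples, by = "biosample_id", all.x = TRUE)
  bio <- merge(bio, repo@donors, by = "donor_id", all.x = TRUE)

  # management chain: item -> case study -> project (null-padded)
  mgm <- merge(ids, repo@caseToItem, by = "item_id", all.x = TRUE)
  mgm <- merge(mgm, repo@caseStudies, by = "case_study_id", all.x = TRUE)
  mgm <- merge(mgm, repo@projects, by = "project_id", all.x = TRUE)

  den <- merge(bio, mgm, by = "item_id")          # R x C paths per item
  den <- merge(den, it, by = "item_id", all.x = TRUE)
  den <- merge(den, repo@experimentTypes, by = "experiment_type_id",
               all.x = TRUE)
  den <- merge(den, repo@datasets, by = "dataset_id", all.x = TRUE)

  den <- den[.DENORM_COLUMNS]
  ord <- order(den$item_id, den$replicate_id, den$case_study_id,
               na.last = TRUE)
  den <- den[ord, , drop = FALSE]
  rownames(den) <- NULL
  den
}
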