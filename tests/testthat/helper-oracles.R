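# Independent oracles and tiny hand-built fixtures shared across tests.
# Oracles deliberately avoid the code paths they check: the closure oracle
# uses igraph shortest paths, the query oracles are plain scans over the
# denormalized records.

# closure oracle: shortest hop distances over the child -> parent digraph
closureOracle <- function(edges, maxDepth) {
  if (is.null(edges) || !nrow(edges))
    return(data.frame(ancestor = integer(0), descendant = integer(0),
                      distance = integer(0)))
  nodes <- sort(unique(c(edges$parent, edges$child)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$child),
               to = as.character(edges$parent)),
    vertices = as.character(nodes))
  d <- igraph::distances(g, mode = "out")
  out <- do.call(rbind, lapply(seq_along(nodes), function(i) {
    anc <- which(is.finite(d[i, ]) & d[i, ] >= 1 & d[i, ] <= maxDepth)
    if (!length(anc)) return(NULL)
    data.frame(ancestor = nodes[anc], descendant = nodes[i],
               distance = as.integer(d[i, anc]))
  }))
  if (is.null(out)) return(data.frame(ancestor = integer(0),
                                      descendant = integer(0),
                                      distance = integer(0)))
  out <- out[order(out$ancestor, out$descendant), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# label resolution oracle: linear scan over all labels
resolveOracle <- function(kb, label) {
  lab <- normalizeValue(label)
  v <- vocabulary(kb); s <- synonyms(kb)
  sort(unique(c(v$tid[!is.na(v$pref_label) & v$pref_label == lab],
                s$tid[!is.na(s$label) & s$label == lab])))
}

# per-(attribute, value, level) accepted raw values, via direct table scans
acceptedValuesOracle <- function(kb, attribute, value, level) {
  v <- normalizeValue(value)
  wanted <- v
  if (level != "original" &&
      attribute %in% searchableAttributes()$attribute[
        searchableAttributes()$enriched]) {
    tids <- resolveOracle(kb, v)
    if (level == "expanded" && length(tids)) {
      cl <- closureOracle(relationships(kb), maxDepth(kb))
      tids <- union(tids, cl$descendant[cl$ancestor %in% tids])
    }
    ann <- annotations(kb)
    wanted <- unique(c(wanted,
                       ann$raw_value[ann$attribute == attribute &
                                       ann$tid %in% tids]))
  }
  wanted
}

# faceted-query oracle: brute-force filter over the denormalized records
queryOracle <- function(repo, kb, selections, level) {
  den <- denormalize(repo)
  ids <- sort(unique(den$item_id))
  for (a in names(selections)) {
    vals <- selections[[a]]
    col <- den[[a]]
    if (a == "age") col <- as.character(col)
    matched <- integer(0)
    for (v in vals) {
      vv <- normalizeValue(v)
      if (!is.na(vv) && vv == ND) {
        matched <- c(matched, den$item_id[is.na(col)])
      } else {
        acc <- acceptedValuesOracle(kb, a, vv, level)
        matched <- c(matched, den$item_id[!is.na(col) & col %in% acc])
      }
    }
    ids <- intersect(ids, sort(unique(matched)))
  }
  sort(unique(ids))
}

# facet-count oracle: recompute the count per value independently
facetOracle <- function(repo, kb, selections, level, attribute) {
  sel <- selections
  sel[[attribute]] <- NULL
  ids <- queryOracle(repo, kb, sel, level)
  den <- denormalize(repo)
  den <- den[den$item_id %in% ids, , drop = FALSE]
  col <- den[[attribute]]
  if (attribute == "age") col <- as.character(col)
  col[is.na(col)] <- ND
  pairs <- unique(paste(den$item_id, col, sep = "\r"))
  vals <- sub("^[^\r]*\r", "", pairs)
  if (!length(vals)) return(setNames(integer(0), character(0)))
  tab <- table(vals)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(-counts, names(counts))]
}

# key-value oracle: row scan over the raw pairs
kvOracle <- function(repo, pairs, exact) {
  rp <- rawPairs(repo)
  hits <- integer(0)
  for (i in seq_len(nrow(rp))) {
    for (k in names(pairs)) {
      kk <- normalizeValue(k)
      km <- if (exact) identical(rp$key[i], kk)
        else !is.na(rp$key[i]) && grepl(kk, rp$key[i], fixed = TRUE)
      if (!km) next
      for (v in normalizeValue(pairs[[k]])) {
        vm <- if (exact) identical(rp$value[i], v)
          else !is.na(rp$value[i]) && grepl(v, rp$value[i], fixed = TRUE)
        if (vm) hits <- c(hits, rp$item_id[i])
      }
    }
  }
  sort(unique(hits))
}

# a small hand-built repository exercising R x C multiplicity and padding
tinyRepository <- function() {
  MetadataRepository(
    donors = data.frame(donor_id = 1:2,
                        donor_source_id = c("don1", "don2"),
                        species = "homo sapiens", age = c(10950L, NA),
                        gender = c("male", "female")),
    biosamples = data.frame(biosample_id = 1:2,
                            biosample_source_id = c("bio1", "bio2"),
                            donor_id = 1:2, tissue = c("Brain", "kidney"),
                            is_healthy = c("true", "false")),
    replicates = data.frame(replicate_id = 1:3,
                            replicate_source_id = c("rep1", "rep2", "rep3"),
                            biosample_id = c(1L, 1L, 2L),
                            biological_replicate_number = c(1L, 2L, 1L)),
    items = data.frame(item_id = 1:4,
                       item_source_id = c("itemA", "itemB", "itemC",
                                          "itemD"),
                       experiment_type_id = 1L, dataset_id = 1L,
                       local_url = c("u1", NA, "u3", NA),
                       source_url = c(NA, "s2", "s3", NA)),
    caseStudies = data.frame(case_study_id = 1:2,
                             case_study_source_id = c("case1", "case2"),
                             project_id = 1L),
    projects = data.frame(project_id = 1L, project_name = "proj one",
                          source = "encode"),
    experimentTypes = data.frame(experiment_type_id = 1L,
                                 technique = "chip-seq",
                                 feature = "histone mark",
                                 target = "h3k4me3"),
    datasets = data.frame(dataset_id = 1L, dataset_name = "ds one",
                          data_type = "peaks", assembly = "grch38",
                          file_format = "bed", is_annotation = "false"),
    # item 1: 2 replicates x 2 cases = 4 paths; item 2: 1 x 1;
    # item 3: replicate but no case; item 4: fully unlinked (annotation-like)
    replicateToItem = data.frame(item_id = c(1L, 1L, 2L, 3L),
                                 replicate_id = c(1L, 2L, 3L, 3L)),
    caseToItem = data.frame(item_id = c(1L, 1L, 2L),
                            case_study_id = c(1L, 2L, 1L)),
    rawPairs = data.frame(item_id = c(1L, 1L, 2L, 3L),
                          key = c("clinical__status", "assay__note",
                                  "clinical__status", "fdr_threshold"),
                          value = c("new tumor event", "Broad Peaks",
                                    "stable", "0.01")))
}

# nested-loop join oracle for denormalization multiplicity
denormOracle <- function(repo) {
  it <- items(repo); r2i <- replicateToItem(repo); c2i <- caseToItem(repo)
  rows <- list()
  for (i in it$item_id) {
    reps <- r2i$replicate_id[r2i$item_id == i]
    if (!length(reps)) reps <- NA_integer_
    cases <- c2i$case_study_id[c2i$item_id == i]
    if (!length(cases)) cases <- NA_integer_
    g <- expand.grid(replicate_id = reps, case_study_id = cases)
    g$item_id <- i
    rows[[length(rows) + 1L]] <- g
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$item_id, out$replicate_id, out$case_study_id,
                   na.last = TRUE), c("item_id", "replicate_id",
                                      "case_study_id")]
  rownames(out) <- NULL
  out
}
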