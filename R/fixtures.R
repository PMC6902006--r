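# Fixture builders: worked examples reconstructed from their printed counts,
# and seeded random repositories with recorded ground truth, so that every
# behavior can be exercised without downloading any real source dump.

# Expand item groups (one row per group, column n = multiplicity, remaining
# columns = attribute assignments) into a full repository where every item
# owns its own donor/biosample/replicate/case chain, so counts are
# unambiguous.
.groupRepository <- function(groups, prefix, rawGroups = NULL) {
  groups <- as.data.frame(groups, stringsAsFactors = FALSE)
  n <- as.integer(groups$n)
  stopifnot(all(n >= 0))
  N <- sum(n)
  gidx <- rep(seq_len(nrow(groups)), n)
  i <- seq_len(N)
  pick <- function(col, default = NA_character_) {
    if (col %in% names(groups)) as.character(groups[[col]])[gidx]
    else rep(default, N)
  }
  donors <- data.frame(
    donor_id = i, donor_source_id = sprintf("%s-don-%06d", prefix, i),
    species = pick("species", "homo sapiens"),
    age = suppressWarnings(as.integer(pick("age"))),
    gender = pick("gender"), ethnicity = pick("ethnicity"))
  biosamples <- data.frame(
    biosample_id = i,
    biosample_source_id = sprintf("%s-bio-%06d", prefix, i),
    donor_id = i, biosample_type = pick("biosample_type"),
    tissue = pick("tissue"), cell = pick("cell"),
    disease = pick("disease"), is_healthy = pick("is_healthy"))
  replicates <- data.frame(
    replicate_id = i, replicate_source_id = sprintf("%s-rep-%06d", prefix, i),
    biosample_id = i, biological_replicate_number = 1L,
    technical_replicate_number = 1L)

  etKey <- paste(pick("technique"), pick("feature"), pick("target"),
                 sep = "\r")
  etLevels <- unique(etKey)
  etId <- match(etKey, etLevels)
  first <- match(etLevels, etKey)
  experimentTypes <- data.frame(
    experiment_type_id = seq_along(etLevels),
    technique = pick("technique")[first], feature = pick("feature")[first],
    target = pick("target")[first], antibody = pick("antibody")[first])

  dsKey <- paste(pick("dataset_name"), pick("data_type"), pick("assembly"),
                 pick("file_format"), sep = "\r")
  dsLevels <- unique(dsKey)
  dsId <- match(dsKey, dsLevels)
  firstDs <- match(dsLevels, dsKey)
  dsNames <- pick("dataset_name")[firstDs]
  dsNames[is.na(dsNames)] <- sprintf("dataset %d", which(is.na(dsNames)))
  datasets <- data.frame(
    dataset_id = seq_along(dsLevels), dataset_name = dsNames,
    data_type = pick("data_type", "peaks")[firstDs],
    assembly = pick("assembly", "grch38")[firstDs],
    file_format = pick("file_format", "bed")[firstDs],
    is_annotation = pick("is_annotation", "false")[firstDs])

  prKey <- paste(pick("project_name"), pick("source"), sep = "\r")
  prLevels <- unique(prKey)
  prId <- match(prKey, prLevels)
  firstPr <- match(prLevels, prKey)
  prNames <- pick("project_name")[firstPr]
  prNames[is.na(prNames)] <- sprintf("project %d", which(is.na(prNames)))
  projects <- data.frame(
    project_id = seq_along(prLevels), project_name = prNames,
    source = pick("source", "encode")[firstPr])
  caseStudies <- data.frame(
    case_study_id = i, case_study_source_id = sprintf("%s-case-%06d",
                                                      prefix, i),
    project_id = prId, source_site = pick("source_site"),
    external_reference = NA_character_)

  items <- data.frame(
    item_id = i, item_source_id = sprintf("%s-item-%06d", prefix, i),
    experiment_type_id = etId, dataset_id = dsId,
    size = 1000 + i, date = "2019-07-01", checksum = NA_character_,
    content_type = pick("content_type"), platform = pick("platform"),
    pipeline = pick("pipeline"),
    source_url = sprintf("https://source.example.org/%s/%06d", prefix, i),
    local_url = sprintf("https://repo.example.org/%s/%06d", prefix, i),
    file_name = sprintf("%s_%06d.bed", prefix, i),
    source_page = NA_character_)

  rawPairs <- NULL
  if ("raw_key" %in% names(groups)) {
    rk <- pick("raw_key"); rv <- pick("raw_value")
    keep <- !is.na(rk)
    if (any(keep))
      rawPairs <- data.frame(item_id = i[keep], key = rk[keep],
                             value = rv[keep])
  }
  if (!is.null(rawGroups)) rawPairs <- rbind(rawPairs, rawGroups)

  MetadataRepository(
    donors = donors, biosamples = biosamples, replicates = replicates,
    items = items, caseStudies = caseStudies, projects = projects,
    experimentTypes = experimentTypes, datasets = datasets,
    replicateToItem = data.frame(item_id = i, replicate_id = i),
    caseToItem = data.frame(item_id = i, case_study_id = i),
    rawPairs = rawPairs)
}

.kbFromTables <- function(terms, synonyms = NULL, edges = NULL,
                          annotations = NULL, maxDepth = 3L) {
  KnowledgeBase(
    vocabulary = data.frame(tid = terms$tid,
                            ontology_source = terms$source,
                            code = terms$code, pref_label = terms$label),
    synonyms = synonyms, relationships = edges, annotations = annotations,
    maxDepth = maxDepth)
}

#' Rebuild a worked example from its printed counts
#'
#' Constructs small, fully self-contained (repository, knowledge base) pairs
#' whose item groups, annotations, synonyms and relationship edges reproduce
#' the published counting examples:
#'
#' * `"uterus"`: items carrying the raw tissue labels of the uterus concept
#'   area (57 uterus, 1651 uterus nos, 9535 corpus uteri, 5417 cervix uteri,
#'   167 cervix, 1 cervical, 21 endometrium, 2 endometrial; 16851 in total)
#'   annotated to the Uberon subtree uterus / body of uterus / uterine
#'   cervix / uterine wall / endometrium with their synonym sets.
#' * `"k562"`: 5942 items with raw cell value `k562` plus 44 labeled
#'   `k562 leukemia cells`, all annotated to EFO_0002067 with its syntactic
#'   variants.
#' * `"boris"`: 10 items with raw target `ctcfl`, annotated to
#'   OGG_3000140690 (preferred label ctcfl, alternative term boris).
#' * `"eye"`: 13 `eye` items, 1440 `eye and adnexa` (synonym of eye) and 20
#'   `retina` items, retina is_a photoreceptor array part_of eye (the two
#'   unprinted term codes use a reserved TEST namespace).
#' * `"brain"`: the deduction-chain example - four raw key-value groups
#'   (789, 4670, 126, 2463 items), core groups (15714 tissue brain, 9188
#'   disease containing brain, 10 cell containing brain, 13 fetal brain
#'   annotated to brain, 10 pons, 8 globus pallidus) and the Uberon edges
#'   pons IS_A regional part of brain PART_OF brain and globus pallidus
#'   PART_OF pallidum IS_A brain gray matter PART_OF brain. Groups are
#'   generated disjoint so each printed chain count is exact.
#' * `"prostate"`: 4821 grch38 prostate adenocarcinoma items split into
#'   3543 non-healthy and 1278 healthy.
#'
#' @param name One of `"uterus"`, `"k562"`, `"boris"`, `"eye"`, `"brain"`,
#'   `"prostate"`.
#' @return List with elements `repository` and `knowledgeBase`.
#' @export
#' @examples
#' ex <- buildWorkedExample("eye")
#' itemCount(ex$repository)
buildWorkedExample <- function(name) {
  builders <- list(uterus = .exampleUterus, k562 = .exampleK562,
                   boris = .exampleBoris, eye = .exampleEye,
                   brain = .exampleBrain, prostate = .exampleProstate)
  if (!name %in% names(builders))
    stop("unknown worked example '", name, "'; available: ",
         paste(names(builders), collapse = ", "), call. = FALSE)
  builders[[name]]()
}

.exampleUterus <- function() {
  terms <- data.frame(
    tid = 1:5, source = "UBERON",
    code = c("UBERON_0000995", "UBERON_0009853", "UBERON_0000002",
             "UBERON_0000459", "UBERON_0001295"),
    label = c("uterus", "body of uterus", "uterine cervix", "uterine wall",
              "endometrium"))
  syns <- data.frame(
    tid = c(1L, 2L, 3L, 3L, 3L, 5L),
    label = c("uterus nos", "corpus uteri", "cervix uteri", "cervix",
              "cervical", "endometrial"),
    syn_type = "alternative syntax")
  edges <- data.frame(parent = c(1L, 1L, 1L, 4L),
                      child = c(2L, 3L, 4L, 5L),
                      rel_type = "PART_OF")
  vals <- c("uterus", "uterus nos", "corpus uteri", "cervix uteri",
            "cervix", "cervical", "endometrium", "endometrial")
  ann <- data.frame(attribute = "tissue", raw_value = vals,
                    tid = c(1L, 1L, 2L, 3L, 3L, 3L, 5L, 5L))
  counts <- c(57L, 1651L, 9535L, 5417L, 167L, 1L, 21L, 2L)
  repo <- .groupRepository(
    data.frame(n = counts, tissue = vals, source = "tcga"), "uterus")
  list(repository = repo,
       knowledgeBase = .kbFromTables(terms, syns, edges, ann))
}

.exampleK562 <- function() {
  terms <- data.frame(tid = 1L, source = "EFO", code = "EFO_0002067",
                      label = "k562")
  syns <- data.frame(tid = 1L,
                     label = c("k-562", "k562 cell", "k-562 cell",
                               "k562 leukemia cells"),
                     syn_type = "alternative syntax")
  ann <- data.frame(attribute = "cell",
                    raw_value = c("k562", "k562 leukemia cells"),
                    tid = 1L)
  repo <- .groupRepository(
    data.frame(n = c(5942L, 44L),
               cell = c("k562", "k562 leukemia cells"),
               source = "encode"), "k562")
  list(repository = repo,
       knowledgeBase = .kbFromTables(terms, syns, annotations = ann))
}

.exampleBoris <- function() {
  terms <- data.frame(tid = 1L, source = "OGG", code = "OGG_3000140690",
                      label = "ctcfl")
  syns <- data.frame(tid = 1L, label = "boris", syn_type = "related term")
  ann <- data.frame(attribute = "target", raw_value = "ctcfl", tid = 1L)
  repo <- .groupRepository(
    data.frame(n = 10L, target = "ctcfl", technique = "chip-seq",
               source = "encode"), "boris")
  list(repository = repo,
       knowledgeBase = .kbFromTables(terms, syns, annotations = ann))
}

.exampleEye <- function() {
  # eye and photoreceptor-array codes are not printed anywhere; synthetic
  # placeholders in a reserved TEST namespace stand in for them
  terms <- data.frame(
    tid = 1:3, source = "TEST",
    code = c("TEST_0000001", "TEST_0000002", "TEST_0000003"),
    label = c("eye", "photoreceptor array", "retina"))
  syns <- data.frame(tid = 1L, label = "eye and adnexa",
                     syn_type = "alternative form")
  edges <- data.frame(parent = c(2L, 1L), child = c(3L, 2L),
                      rel_type = c("IS_A", "PART_OF"))
  ann <- data.frame(attribute = "tissue",
                    raw_value = c("eye", "eye and adnexa", "retina"),
                    tid = c(1L, 1L, 3L))
  repo <- .groupRepository(
    data.frame(n = c(13L, 1440L, 20L),
               tissue = c("eye", "eye and adnexa", "retina"),
               source = c("encode", "tcga", "encode")), "eye")
  list(repository = repo,
       knowledgeBase = .kbFromTables(terms, syns, edges, ann))
}

.exampleBrain <- function() {
  terms <- data.frame(
    tid = 1:6, source = "UBERON",
    code = c("UBERON_0000955", "UBERON_0000988", "UBERON_0002616",
             "UBERON_0001875", "UBERON_0006514", "UBERON_0003528"),
    label = c("brain", "pons", "regional part of brain", "globus pallidus",
              "pallidum", "brain gray matter"))
  edges <- data.frame(
    parent = c(3L, 1L, 5L, 6L, 1L),
    child = c(2L, 3L, 4L, 5L, 6L),
    rel_type = c("IS_A", "PART_OF", "PART_OF", "IS_A", "PART_OF"))
  ann <- data.frame(
    attribute = c("tissue", "cell", "tissue", "tissue"),
    raw_value = c("brain", "fetal brain", "pons", "globus pallidus"),
    tid = c(1L, 1L, 2L, 4L))
  groups <- data.frame(
    n = c(15714L, 9188L, 10L, 13L, 10L, 8L,
          789L, 4670L, 126L, 2463L),
    tissue = c("brain", NA, NA, NA, "pons", "globus pallidus",
               NA, NA, NA, NA),
    disease = c(NA, "brain lower grade glioma", NA, NA, NA, NA,
                NA, NA, NA, NA),
    cell = c(NA, NA, "smooth muscle cell of the brain vasculature",
             "fetal brain", NA, NA, NA, NA, NA, NA),
    raw_key = c(NA, NA, NA, NA, NA, NA,
                "biosample__organ_slims", "gdc__project__disease_type",
                "clinical__lgg__family_history_of_primary_brain_tumor",
                "clinical_patient__history_lgg_dx_of_brain_tissue"),
    raw_value = c(NA, NA, NA, NA, NA, NA,
                  "brain", "brain lower grade glioma", "yes", "no"),
    source = c("encode", "tcga", "encode", "encode", "roadmap epigenomics",
               "roadmap epigenomics", "tcga", "tcga", "tcga", "tcga"))
  repo <- .groupRepository(groups, "brain")
  list(repository = repo,
       knowledgeBase = .kbFromTables(terms, edges = edges,
                                     annotations = ann))
}

.exampleProstate <- function() {
  repo <- .groupRepository(
    data.frame(n = c(3543L, 1278L),
               disease = "prostate adenocarcinoma",
               assembly = "grch38",
               is_healthy = c("false", "true"),
               tissue = "prostate gland",
               source = "tcga", project_name = "tcga-prad"), "prostate")
  list(repository = repo, knowledgeBase = KnowledgeBase())
}

# --- seeded random repositories with ground truth ----------------------------

#' Seeded random repository with recorded ground truth
#'
#' Generates a deterministic random repository and knowledge base: a random
#' ontology DAG (each term may have several parents among earlier terms,
#' so the graph is acyclic by construction), random value pools for enriched
#' and plain attributes with a configurable annotation rate, items with 0-2
#' replicates and 0-2 case studies (so null padding and combined items
#' occur), and random raw key-value pairs. For a sample of (attribute,
#' value, level) probes the exact expected answer is computed at generation
#' time by an independent brute-force pass over the entity tables (no joins,
#' no closure), and recorded in the returned ground truth. Optionally a
#' number of integrity corruptions (duplicate source ids, dangling foreign
#' keys, negative ages, illegal tri-state values) is injected after the
#' probes are recorded, each producing exactly one validation violation.
#'
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @param nItems Number of items.
#' @param nTerms Ontology size.
#' @param nValuesPerAttribute Pool size per enriched attribute.
#' @param annotationRate Probability that a pool value is annotated.
#' @param maxRawPairsPerItem Upper bound of raw pairs per item.
#' @param corruptionCount Number of integrity corruptions to inject (probes
#'   always reflect the uncorrupted repository).
#' @param nProbes Number of ground-truth probes to record.
#' @param maxDepth Closure depth bound.
#' @return List with `repository`, `knowledgeBase` and `truth` (a list with
#'   `probes`: data.frame of attribute/value/level plus list-column
#'   `expected` of item-id vectors; and `corruptions`: data.frame of the
#'   injected corruptions).
#' @export
#' @examples
#' fx <- randomRepository(1, nItems = 30)
#' nrow(fx$truth$probes)
randomRepository <- function(seed, nItems = 100L, nTerms = 25L,
                             nValuesPerAttribute = 6L, annotationRate = 0.6,
                             maxRawPairsPerItem = 3L, corruptionCount = 0L,
                             nProbes = 12L, maxDepth = 3L) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  nItems <- as.integer(nItems)

  # ontology: parents always have a smaller tid -> acyclic
  terms <- data.frame(tid = seq_len(nTerms), source = "RND",
                      code = sprintf("RND_%07d", seq_len(nTerms)),
                      label = sprintf("term %03d", seq_len(nTerms)))
  syn <- which(stats::runif(nTerms) < 0.5)
  synonyms <- if (length(syn))
    data.frame(tid = syn, label = sprintf("alt label %03d", syn),
               syn_type = "alternative syntax") else NULL
  edges <- NULL
  for (t in 2:nTerms) {
    k <- sample(0:2, 1, prob = c(0.25, 0.55, 0.20))
    if (!k) next
    par <- sample(seq_len(t - 1L), min(k, t - 1L))
    edges <- rbind(edges, data.frame(
      parent = par, child = t,
      rel_type = sample(c("IS_A", "PART_OF"), length(par), replace = TRUE)))
  }

  enr <- c("tissue", "cell", "disease", "target")
  pools <- list()
  ann <- NULL
  for (a in enr) {
    vals <- sprintf("%s value %02d", a, seq_len(nValuesPerAttribute))
    pools[[a]] <- vals
    hit <- stats::runif(length(vals)) < annotationRate
    if (any(hit))
      ann <- rbind(ann, data.frame(
        attribute = a, raw_value = vals[hit],
        tid = sample(seq_len(nTerms), sum(hit), replace = TRUE)))
  }
  kb <- .kbFromTables(terms, synonyms, edges, ann, maxDepth = maxDepth)

  if (nItems == 0L) {
    return(list(repository = MetadataRepository(), knowledgeBase = kb,
                truth = list(probes = data.frame(), corruptions = data.frame())))
  }

  maybeNA <- function(x, p) { x[stats::runif(length(x)) < p] <- NA; x }
  nDonors <- max(2L, as.integer(ceiling(nItems * 0.6)))
  donors <- data.frame(
    donor_id = seq_len(nDonors),
    donor_source_id = sprintf("rnd-don-%06d", seq_len(nDonors)),
    species = "homo sapiens",
    age = maybeNA(sample.int(30000L, nDonors, replace = TRUE), 0.2),
    gender = maybeNA(sample(c("male", "female"), nDonors, TRUE), 0.1),
    ethnicity = NA_character_)
  nBios <- nDonors
  biosamples <- data.frame(
    biosample_id = seq_len(nBios),
    biosample_source_id = sprintf("rnd-bio-%06d", seq_len(nBios)),
    donor_id = sample(seq_len(nDonors), nBios, replace = TRUE),
    biosample_type = sample(c("tissue", "cell line", "primary cell"),
                            nBios, TRUE),
    tissue = maybeNA(sample(pools$tissue, nBios, TRUE), 0.15),
    cell = maybeNA(sample(pools$cell, nBios, TRUE), 0.3),
    disease = maybeNA(sample(pools$disease, nBios, TRUE), 0.3),
    is_healthy = sample(c("true", "false", NA), nBios, TRUE))
  nReps <- max(2L, as.integer(ceiling(nItems * 0.8)))
  replicates <- data.frame(
    replicate_id = seq_len(nReps),
    replicate_source_id = sprintf("rnd-rep-%06d", seq_len(nReps)),
    biosample_id = sample(seq_len(nBios), nReps, replace = TRUE),
    biological_replicate_number = sample(1:2, nReps, TRUE),
    technical_replicate_number = 1L)

  techniques <- c("chip-seq", "dnase-seq", "rna-seq", "wxs")
  ets <- expand.grid(technique = techniques,
                     target = c(pools$target, NA),
                     stringsAsFactors = FALSE)
  experimentTypes <- data.frame(
    experiment_type_id = seq_len(nrow(ets)),
    technique = ets$technique, feature = "binding site",
    target = ets$target, antibody = NA_character_)
  datasets <- data.frame(
    dataset_id = 1:4,
    dataset_name = sprintf("rnd dataset %d", 1:4),
    data_type = sample(c("peaks", "expression", "mutation"), 4, TRUE),
    assembly = c("hg19", "grch38", "hg19", "grch38"),
    file_format = sample(c("bed", "narrowpeak"), 4, TRUE),
    is_annotation = c("false", "false", "false", "true"))
  projects <- data.frame(
    project_id = 1:3, project_name = sprintf("rnd project %d", 1:3),
    source = sample(c("tcga", "encode", "roadmap epigenomics"), 3))
  nCases <- max(2L, as.integer(ceiling(nItems / 3)))
  caseStudies <- data.frame(
    case_study_id = seq_len(nCases),
    case_study_source_id = sprintf("rnd-case-%06d", seq_len(nCases)),
    project_id = sample(1:3, nCases, replace = TRUE),
    source_site = NA_character_, external_reference = NA_character_)

  items <- data.frame(
    item_id = seq_len(nItems),
    item_source_id = sprintf("rnd-item-%06d", seq_len(nItems)),
    experiment_type_id = sample(seq_len(nrow(ets)), nItems, replace = TRUE),
    dataset_id = sample(1:4, nItems, replace = TRUE),
    size = sample.int(1e6L, nItems, replace = TRUE),
    date = "2019-07-01", checksum = NA_character_,
    content_type = NA_character_, platform = NA_character_,
    pipeline = maybeNA(sample(c("hotspot", "macs2"), nItems, TRUE), 0.5),
    source_url = sprintf("https://source.example.org/rnd/%06d",
                         seq_len(nItems)),
    local_url = maybeNA(sprintf("https://repo.example.org/rnd/%06d",
                                seq_len(nItems)), 0.2),
    file_name = sprintf("rnd_%06d.bed", seq_len(nItems)),
    source_page = NA_character_)

  r2i <- do.call(rbind, lapply(seq_len(nItems), function(it) {
    k <- sample(0:2, 1, prob = c(0.1, 0.7, 0.2))
    if (!k) return(NULL)
    data.frame(item_id = it, replicate_id = sample(seq_len(nReps), k))
  }))
  c2i <- do.call(rbind, lapply(seq_len(nItems), function(it) {
    k <- sample(0:2, 1, prob = c(0.05, 0.8, 0.15))
    if (!k) return(NULL)
    data.frame(item_id = it, case_study_id = sample(seq_len(nCases), k))
  }))

  rawKeys <- c("biospecimen__admin__disease_code",
               "clinical__shared__history", "manually_curated__fdr_threshold",
               "gdc__project__disease_type", "biosample__organ_slims")
  rawVals <- c("chol", "kich", "primary tumor", "0.01", "none", "yes", "no",
               "brain", "new tumor event")
  rp <- do.call(rbind, lapply(seq_len(nItems), function(it) {
    k <- sample(0:maxRawPairsPerItem, 1)
    if (!k) return(NULL)
    unique(data.frame(item_id = it,
                      key = sample(rawKeys, k, replace = TRUE),
                      value = sample(rawVals, k, replace = TRUE)))
  }))

  tables <- list(donors = donors, biosamples = biosamples,
                 replicates = replicates, items = items,
                 caseStudies = caseStudies, projects = projects,
                 experimentTypes = experimentTypes, datasets = datasets,
                 replicateToItem = r2i, caseToItem = c2i, rawPairs = rp)

  # ground-truth probes, brute-forced over the clean tables
  probeAttrs <- c(enr, "assembly", "is_healthy")
  probes <- data.frame(
    attribute = sample(probeAttrs, nProbes, replace = TRUE),
    level = sample(.SEMANTIC_LEVELS, nProbes, replace = TRUE),
    stringsAsFactors = FALSE)
  probes$value <- vapply(probes$attribute, function(a) {
    pool <- switch(a, assembly = c("hg19", "grch38"),
                   is_healthy = c("true", "false"),
                   c(pools[[a]], sprintf("alt label %03d",
                                         seq_len(nTerms))))
    sample(c(pool, ND), 1, prob = c(rep(1, length(pool)), 0.5))
  }, character(1))
  probes$expected <- lapply(seq_len(nProbes), function(i)
    .bruteForceMatch(tables, terms, synonyms, edges, ann,
                     probes$attribute[i], probes$value[i], probes$level[i],
                     maxDepth))

  corruptions <- .injectCorruptions(tables, as.integer(corruptionCount))
  tables <- corruptions$tables

  list(repository = do.call(MetadataRepository, tables),
       knowledgeBase = kb,
       truth = list(probes = probes, corruptions = corruptions$log))
}

# Independent brute-force matcher used only at generation time: works on the
# raw entity tables with explicit id set chasing (no denormalized view, no
# materialized closure).
.bruteForceMatch <- function(tables, terms, synonyms, edges, ann,
                             attribute, value, level, maxDepth) {
  v <- .normalizeValue(value)
  entity <- .ATTRIBUTE_REGISTRY$entity[
    match(attribute, .ATTRIBUTE_REGISTRY$attribute)]
  tabName <- c(donor = "donors", biosample = "biosamples", item = "items",
               experiment_type = "experimentTypes", dataset = "datasets",
               case_study = "caseStudies", project = "projects")[[entity]]
  tab <- tables[[tabName]]
  col <- .normalizeValue(as.character(tab[[attribute]]))

  wanted <- v
  isND <- !is.na(v) && v == ND
  if (!isND && level != "original" &&
      attribute %in% .enrichedAttributes() && !is.null(ann)) {
    labs <- c(.normalizeValue(terms$label),
              if (!is.null(synonyms)) .normalizeValue(synonyms$label))
    tids <- c(terms$tid, if (!is.null(synonyms)) synonyms$tid)[labs == v]
    tids <- unique(tids[!is.na(tids)])
    if (level == "expanded" && length(tids) && !is.null(edges)) {
      # iterative downward expansion, one level at a time
      frontier <- tids
      all <- tids
      for (d in seq_len(maxDepth)) {
        frontier <- unique(edges$child[edges$parent %in% frontier])
        frontier <- setdiff(frontier, all)
        if (!length(frontier)) break
        all <- c(all, frontier)
      }
      tids <- all
    }
    more <- .normalizeValue(
      ann$raw_value[ann$attribute == attribute & ann$tid %in% tids])
    wanted <- unique(c(wanted, more))
  }

  rowHit <- if (isND) is.na(col) else (!is.na(col) & col %in% wanted)
  # chase rows up to item ids through the schema
  itemsOfBiosample <- function(bids, hitNA) {
    reps <- tables$replicates
    rids <- reps$replicate_id[reps$biosample_id %in% bids]
    r2i <- tables$replicateToItem
    ids <- r2i$item_id[r2i$replicate_id %in% rids]
    if (hitNA) {
      # items with no replicate at all surface a null attribute
      noRep <- setdiff(tables$items$item_id, r2i$item_id)
      ids <- c(ids, noRep)
    }
    ids
  }
  ids <- switch(entity,
    biosample = itemsOfBiosample(tab$biosample_id[rowHit], isND),
    donor = {
      dids <- tab$donor_id[rowHit]
      bios <- tables$biosamples
      bids <- bios$biosample_id[bios$donor_id %in% dids]
      extra <- isND
      itemsOfBiosample(bids, extra)
    },
    item = tables$items$item_id[rowHit],
    experiment_type = {
      eids <- tab$experiment_type_id[rowHit]
      tables$items$item_id[tables$items$experiment_type_id %in% eids]
    },
    dataset = {
      dids <- tab$dataset_id[rowHit]
      tables$items$item_id[tables$items$dataset_id %in% dids]
    },
    case_study = {
      cids <- tab$case_study_id[rowHit]
      c2i <- tables$caseToItem
      ids <- c2i$item_id[c2i$case_study_id %in% cids]
      if (isND) ids <- c(ids, setdiff(tables$items$item_id, c2i$item_id))
      ids
    },
    project = {
      pids <- tab$project_id[rowHit]
      cs <- tables$caseStudies
      cids <- cs$case_study_id[cs$project_id %in% pids]
      c2i <- tables$caseToItem
      ids <- c2i$item_id[c2i$case_study_id %in% cids]
      if (isND) ids <- c(ids, setdiff(tables$items$item_id, c2i$item_id))
      ids
    })
  .idset(ids)
}

.injectCorruptions <- function(tables, count) {
  log <- data.frame(type = character(0), table = character(0),
                    row = integer(0))
  if (count < 1L) return(list(tables = tables, log = log))
  types <- rep(c("duplicate_source_id", "dangling_fk", "negative_age",
                 "illegal_tristate"), length.out = count)
  usedDon <- 0L; usedBio <- 0L
  for (i in seq_len(count)) {
    switch(types[i],
      duplicate_source_id = {
        a <- usedDon + 1L; b <- usedDon + 2L; usedDon <- usedDon + 2L
        stopifnot(b <= nrow(tables$donors))
        tables$donors$donor_source_id[b] <- tables$donors$donor_source_id[a]
        log <- rbind(log, data.frame(type = types[i], table = "donors",
                                     row = b))
      },
      dangling_fk = {
        usedBio <- usedBio + 1L
        stopifnot(usedBio <= nrow(tables$biosamples))
        tables$biosamples$donor_id[usedBio] <- 1000000L + i
        log <- rbind(log, data.frame(type = types[i], table = "biosamples",
                                     row = usedBio))
      },
      negative_age = {
        usedDon <- usedDon + 1L
        stopifnot(usedDon <= nrow(tables$donors))
        tables$donors$age[usedDon] <- -i
        log <- rbind(log, data.frame(type = types[i], table = "donors",
                                     row = usedDon))
      },
      illegal_tristate = {
        usedBio <- usedBio + 1L
        stopifnot(usedBio <= nrow(tables$biosamples))
        tables$biosamples$is_healthy[usedBio] <- sprintf("maybe%d", i)
        log <- rbind(log, data.frame(type = types[i], table = "biosamples",
                                     row = usedBio))
      })
  }
  list(tables = tables, log = log)
}
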