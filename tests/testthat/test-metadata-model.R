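# Core schema: construction, normalization, denormalization, validation, I/O.

test_that("empty inputs give an empty but well-formed repository", {
  repo <- MetadataRepository()
  expect_s4_class(repo, "MetadataRepository")
  expect_identical(itemCount(repo), 0L)
  expect_identical(nrow(denormalizedView(repo)), 0L)
  expect_identical(nrow(validateRepository(repo)), 0L)
})

test_that("values are normalized at load: case, whitespace, empties", {
  repo <- tinyRepository()
  expect_identical(biosamples(repo)$tissue[1], "brain")
  expect_identical(rawPairs(repo)$value[2], "broad peaks")
  expect_true(all(c("tissue_tid", "cell_tid") %in%
                    names(biosamples(repo))))
})

test_that("denormalization follows the R x C multiplicity rule with padding", {
  repo <- tinyRepository()
  den <- denormalizedView(repo)
  expect_identical(sum(den$item_id == 1L), 4L)  # 2 replicates x 2 cases
  expect_identical(sum(den$item_id == 2L), 1L)
  expect_identical(sum(den$item_id == 3L), 1L)  # padded case side
  expect_true(is.na(den$case_study_id[den$item_id == 3L]))
  expect_identical(sum(den$item_id == 4L), 1L)  # fully padded
  # item set is conserved
  expect_setequal(unique(den$item_id), items(repo)$item_id)
  # every core searchable attribute appears exactly once per row
  expect_true(all(searchableAttributes()$attribute %in% names(den)))
  expect_false(anyDuplicated(names(den)) > 0)
})

test_that("denormalization agrees with a nested-loop join oracle", {
  for (seed in c(3, 17, 44)) {
    fx <- randomRepository(seed, nItems = 40)
    den <- denormalizedView(fx$repository)[, c("item_id", "replicate_id",
                                               "case_study_id")]
    rownames(den) <- NULL
    expect_identical(den, denormOracle(fx$repository))
  }
})

test_that("validateRepository is empty on valid data and flags each defect", {
  repo <- tinyRepository()
  expect_identical(nrow(validateRepository(repo)), 0L)

  dup <- donors(repo)
  dup$donor_source_id[2] <- dup$donor_source_id[1]
  bad <- MetadataRepository(donors = dup, biosamples = biosamples(repo),
                            replicates = replicates(repo),
                            items = items(repo),
                            caseStudies = caseStudies(repo),
                            projects = projects(repo),
                            experimentTypes = experimentTypes(repo),
                            datasets = datasets(repo),
                            replicateToItem = replicateToItem(repo),
                            caseToItem = caseToItem(repo),
                            rawPairs = rawPairs(repo))
  rep <- validateRepository(bad)
  expect_identical(nrow(rep), 1L)
  expect_identical(rep$rule, "duplicate_source_id")
})

test_that("seeded corruption injection yields exactly one violation each", {
  for (seed in c(5, 23)) {
    fx <- randomRepository(seed, nItems = 60, corruptionCount = 6)
    report <- validateRepository(fx$repository)
    expect_identical(nrow(report), nrow(fx$truth$corruptions))
    expect_identical(nrow(fx$truth$corruptions), 6L)
  }
})

test_that("store then load round-trips the repository field by field", {
  fx <- randomRepository(9, nItems = 50)
  d <- tempfile("repo")
  writeRepository(fx$repository, d)
  back <- loadRepository(d)
  for (nm in c("donors", "biosamples", "replicates", "items", "caseStudies",
               "projects", "experimentTypes", "datasets"))
    expect_equal(slot(back, nm), slot(fx$repository, nm), info = nm)
  expect_equal(denormalizedView(back), denormalizedView(fx$repository))

  kd <- tempfile("kb")
  writeKnowledgeBase(fx$knowledgeBase, kd)
  kbBack <- loadKnowledgeBase(kd)
  expect_equal(vocabulary(kbBack), vocabulary(fx$knowledgeBase))
  expect_equal(termClosure(kbBack), termClosure(fx$knowledgeBase))
})

test_that("loading a dump with a dangling FK raises an integrity error", {
  fx <- randomRepository(13, nItems = 30)
  d <- tempfile("repo")
  writeRepository(fx$repository, d)
  reps <- read.table(file.path(d, "replicates.tsv"), sep = "\t",
                     header = TRUE, na.strings = "")
  reps$biosample_id[1] <- 999999L
  write.table(reps, file.path(d, "replicates.tsv"), sep = "\t",
              quote = FALSE, na = "", row.names = FALSE)
  expect_error(loadRepository(d), "integrity error.*biosample_id=999999")
  # but the broken dump can still be loaded for diagnosis
  repo <- loadRepository(d, check = FALSE)
  expect_gt(nrow(validateRepository(repo)), 0)
})

test_that("a dump missing a mandatory column raises a format error", {
  fx <- randomRepository(2, nItems = 10)
  d <- tempfile("repo")
  writeRepository(fx$repository, d)
  it <- read.table(file.path(d, "items.tsv"), sep = "\t", header = TRUE,
                   na.strings = "")
  it$item_id <- NULL
  write.table(it, file.path(d, "items.tsv"), sep = "\t", quote = FALSE,
              na = "", row.names = FALSE)
  expect_error(loadRepository(d), "format error.*item_id")
})
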