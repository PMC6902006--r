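# REST-contract response functions and exports.

prostateEx <- buildWorkedExample("prostate")

test_that("field counts reproduce the documented response shape", {
  payload <- paste0('{"gcm": {"disease": ["prostate adenocarcinoma"],',
                    ' "assembly": ["grch38"]}, "type": "original",',
                    ' "kv": {}}')
  res <- fieldCounts(prostateEx$repository, prostateEx$knowledgeBase,
                     payload, "is_healthy")
  expect_identical(res$info$item_count, 4821L)
  expect_identical(res$info$shown_count, 2L)
  expect_identical(res$info$total_count, 2L)
  expect_identical(res$values[[1]], list(value = FALSE, count = 3543L))
  expect_identical(res$values[[2]], list(value = TRUE, count = 1278L))
  # byte-identical across calls (pure function of repo, kb, payload)
  j1 <- fieldCountsJSON(prostateEx$repository, prostateEx$knowledgeBase,
                        payload, "is_healthy")
  j2 <- fieldCountsJSON(prostateEx$repository, prostateEx$knowledgeBase,
                        payload, "is_healthy")
  expect_identical(j1, j2)
  expect_error(fieldCounts(prostateEx$repository, prostateEx$knowledgeBase,
                           payload, "not_a_field"), "not a searchable")
})

test_that("field counts on an empty repository are empty", {
  res <- fieldCounts(MetadataRepository(), KnowledgeBase(),
                     '{"gcm": {}, "kv": {}}', "is_healthy")
  expect_identical(res$info$item_count, 0L)
  expect_length(res$values, 0L)
})

test_that("field counts equal facetCounts computed within the context", {
  fx <- randomRepository(33, nItems = 60)
  payload <- '{"gcm": {"assembly": ["grch38"]}, "type": "original", "kv": {}}'
  res <- fieldCounts(fx$repository, fx$knowledgeBase, payload, "is_healthy")
  oracle <- facetOracle(fx$repository, fx$knowledgeBase,
                        list(assembly = "grch38"), "original", "is_healthy")
  oracle <- oracle[names(oracle) != ND]
  got <- setNames(
    vapply(res$values, function(v) v$count, integer(1)),
    vapply(res$values, function(v) tolower(as.character(v$value)),
           character(1)))
  expect_identical(got, oracle)
})

test_that("link export prefers local URLs and orders by source id", {
  repo <- tinyRepository()
  expect_identical(exportLinks(repo, ResultSet()), "")
  out <- exportLinks(repo, ResultSet(1:4))
  # item 4 has no URL at all and is skipped
  expect_identical(strsplit(out, "\n")[[1]], c("u1", "s2", "u3"))
})

test_that("CSV export round-trips and groups rows by the sort key", {
  repo <- tinyRepository()
  csv <- exportTable(repo, ResultSet(1:4), mode = "replicated",
                     sortKeys = c("donor_source_id", "item_source_id"))
  parsed <- read.csv(text = csv, colClasses = "character", na.strings = "")
  expect_identical(nrow(parsed), nrow(denormalizedView(repo)))
  # same-donor rows are adjacent
  d <- parsed$donor_source_id[!is.na(parsed$donor_source_id)]
  expect_identical(d, sort(d))
  # header-only for an empty result
  empty <- exportTable(repo, ResultSet())
  expect_identical(length(strsplit(empty, "\n")[[1]]), 1L)
  # quoting survives commas in values
  repo2 <- MetadataRepository(
    items = data.frame(item_id = 1L, item_source_id = "a,b",
                       experiment_type_id = NA, dataset_id = NA))
  parsed2 <- read.csv(text = exportTable(repo2, ResultSet(1L)),
                      colClasses = "character")
  expect_identical(parsed2$item_source_id, "a,b")
})
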