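# JSON query dialect and the human-readable selected-query rendering.

test_that("a faceted payload parses into a one-step session", {
  s <- parseQuery(paste0(
    '{"gcm": {"disease": ["prostate adenocarcinoma"],',
    ' "assembly": ["grch38"]}, "type": "original", "kv": {}}'))
  expect_s4_class(s, "QuerySession")
  expect_identical(sessionLevel(s), "original")
  expect_length(sessionSteps(s), 1L)
  sel <- querySelections(sessionSteps(s)[[1]])
  expect_identical(sel$disease, "prostate adenocarcinoma")
  expect_identical(sel$assembly, "grch38")
})

test_that("an empty document parses to a session matching all items", {
  s <- parseQuery('{"gcm": {}, "type": "original", "kv": {}}')
  ex <- buildWorkedExample("boris")
  expect_identical(length(evaluateSession(ex$repository, ex$knowledgeBase, s)),
                   itemCount(ex$repository))
  # type defaults to original when absent
  expect_identical(sessionLevel(parseQuery('{"gcm": {}}')), "original")
})

test_that("kv entries become key-value steps with their flags", {
  s <- parseQuery(paste0(
    '{"gcm": {"source": ["roadmap epigenomics"], "technique": ["dnase-seq"],',
    ' "pipeline": ["hotspot"], "cell": ["h1 cells"]}, "type": "synonym",',
    ' "kv": {"fdr_0": {"type_query": "key", "exact": false,',
    ' "query": {"gcm": {}, "pairs":',
    ' {"manually_curated__fdr_threshold": ["0.01"]}}}}}'))
  expect_identical(sessionLevel(s), "synonym")
  expect_length(sessionSteps(s), 2L)
  step2 <- sessionSteps(s)[[2]]
  expect_true(is.list(step2) && is(step2[[1]], "KeyValuePredicate"))
  expect_false(step2[[1]]@exact)
  expect_identical(step2[[1]]@pairs$manually_curated__fdr_threshold, "0.01")
})

test_that("bad level strings and unknown attributes are parse errors", {
  expect_error(parseQuery('{"gcm": {}, "type": "riginal", "kv": {}}'),
               "parse error at type")
  expect_error(parseQuery('{"gcm": {"bogus": ["x"]}, "kv": {}}'),
               "parse error at gcm.bogus")
  expect_error(parseQuery('{"gcm": '), "parse error")
})

test_that("serialize/parse round-trips random query documents", {
  set.seed(42)
  attrs <- c("tissue", "cell", "disease", "assembly", "source", "target")
  keys <- c("clinical__status", "biospecimen__admin__disease_code",
            "manually_curated__fdr_threshold")
  for (rep in 1:25) {
    sel <- lapply(seq_len(sample(0:3, 1)), function(i)
      sprintf("value %02d", sample(1:30, sample(1:2, 1))))
    names(sel) <- sample(attrs, length(sel))
    steps <- list(FacetedQuery(sel))
    for (k in seq_len(sample(0:2, 1))) {
      pairs <- lapply(seq_len(sample(1:2, 1)), function(i)
        sprintf("raw value %02d", sample(1:20, sample(1:2, 1))))
      names(pairs) <- sample(keys, length(pairs))
      steps[[length(steps) + 1L]] <- KeyValuePredicate(
        pairs = pairs, exact = sample(c(TRUE, FALSE), 1),
        mode = sample(c("key", "value"), 1),
        name = sprintf("step_%d", k))
    }
    s <- QuerySession(steps, level = sample(semanticLevels(), 1))
    back <- parseQuery(serializeQuery(s))
    expect_equal(back, s, info = paste("round trip", rep))
    # and a second pass is byte-stable
    expect_identical(serializeQuery(back), serializeQuery(s))
  }
})

test_that("the selected-query string uses registry order and brackets", {
  q <- FacetedQuery(tissue = "kidney",
                    data_type = c("copy number segment",
                                  "masked copy number segment"),
                    assembly = "grch38")
  expect_identical(
    renderSelectedQuery(q),
    paste0("assembly: [grch38], data_type: [copy number segment, ",
           "masked copy number segment], tissue: [kidney]"))
  expect_identical(renderSelectedQuery(FacetedQuery()), "")
  # re-parseable by an inverse grammar
  parsed <- strsplit(strsplit(renderSelectedQuery(q), "\\], ")[[1]], ": \\[")
  expect_identical(vapply(parsed, `[`, "", 1),
                   c("assembly", "data_type", "tissue"))
})

test_that("the shipped predefined queries all parse", {
  qdir <- system.file("extdata", "queries", package = "GenoFacet")
  files <- list.files(qdir, pattern = "\\.json$", full.names = TRUE)
  expect_identical(length(files), 10L)
  for (f in files) expect_s4_class(parseQuery(f), "QuerySession")
})
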