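# Faceted search, key-value search, sessions, facet counts, summarization.

uterusEx <- buildWorkedExample("uterus")

test_that("semantic levels widen results exactly as the uterus area shows", {
  repo <- uterusEx$repository; kb <- uterusEx$knowledgeBase
  m <- function(v, l) length(matchItems(repo, kb, "tissue", v, l))
  expect_identical(m("uterus", "original"), 57L)
  expect_identical(m("uterus", "synonym"), 1708L)
  expect_identical(m("uterus", "expanded"), 16851L)
  expect_identical(m("nonexistent", "original"), 0L)
  expect_identical(m("nonexistent", "expanded"), 0L)
  # synonym level equals the sum of the disjoint original groups it covers
  expect_identical(m("uterus", "synonym"),
                   m("uterus", "original") + m("uterus nos", "original"))
  expect_identical(m("cervical", "synonym"),
                   m("cervix uteri", "original") + m("cervix", "original") +
                     m("cervical", "original"))
  expect_error(matchItems(repo, kb, "nope", "x", "original"),
               "not a searchable attribute")
})

test_that("level monotonicity holds for every probe on random fixtures", {
  for (seed in c(2, 19, 40)) {
    fx <- randomRepository(seed, nItems = 80)
    probes <- fx$truth$probes
    for (i in seq_len(nrow(probes))) {
      o <- matchItems(fx$repository, fx$knowledgeBase,
                      probes$attribute[i], probes$value[i], "original")
      s <- matchItems(fx$repository, fx$knowledgeBase,
                      probes$attribute[i], probes$value[i], "synonym")
      e <- matchItems(fx$repository, fx$knowledgeBase,
                      probes$attribute[i], probes$value[i], "expanded")
      expect_true(all(o %in% s) && all(s %in% e),
                  info = paste(seed, probes$attribute[i], probes$value[i]))
    }
  }
})

test_that("evaluateQuery is conjunctive across attributes, disjunctive within", {
  repo <- tinyRepository(); kb <- KnowledgeBase()
  all4 <- itemIds(evaluateQuery(repo, kb, FacetedQuery(), "original"))
  expect_identical(all4, 1:4)
  r <- evaluateQuery(repo, kb, FacetedQuery(tissue = c("brain", "kidney"),
                                            assembly = "grch38"), "original")
  expect_identical(itemIds(r), 1:3)
  r2 <- evaluateQuery(repo, kb, FacetedQuery(tissue = "brain",
                                             is_healthy = "false"),
                      "original")
  expect_identical(length(r2), 0L)
  # ND selects the padded/null items
  rNd <- evaluateQuery(repo, kb, FacetedQuery(tissue = ND), "original")
  expect_identical(itemIds(rNd), 4L)
  expect_error(
    evaluateQuery(repo, kb, FacetedQuery(tissue = c("brain", ND)), "synonym"),
    "cannot be combined")
  # age bound pseudo-attribute: 30 years -> 10950 days matches donor 1 only
  # only item 1 reaches the donor with a recorded age of 10950 days
  rAge <- evaluateQuery(repo, kb, FacetedQuery(max_age = "10950"),
                        "original")
  expect_identical(itemIds(rAge), 1L)
})

test_that("query, session and facet counts agree with brute-force oracles", {
  attrsPool <- c("tissue", "cell", "disease", "target", "assembly",
                 "is_healthy", "source")
  for (seed in c(7, 12, 28, 51)) {
    fx <- randomRepository(seed, nItems = 70)
    repo <- fx$repository; kb <- fx$knowledgeBase
    den <- denormalizedView(repo)
    set.seed(seed * 100)
    for (rep in 1:3) {
      level <- sample(semanticLevels(), 1)
      nA <- sample(1:3, 1)
      attrs <- sample(attrsPool, nA)
      sel <- lapply(attrs, function(a) {
        pool <- unique(den[[a]])
        pool <- pool[!is.na(pool)]
        if (!length(pool)) return(ND)
        unique(c(sample(pool, min(length(pool), sample(1:2, 1)))))
      })
      names(sel) <- attrs
      got <- itemIds(evaluateQuery(repo, kb, FacetedQuery(sel), level))
      expect_identical(got, queryOracle(repo, kb, sel, level),
                       info = paste("query", seed, rep))
      a <- sample(attrsPool, 1)
      expect_identical(facetCounts(repo, kb, FacetedQuery(sel), level, a),
                       facetOracle(repo, kb, sel, level, a),
                       info = paste("facet", seed, rep))
    }
  }
})

test_that("facet counts use self-exclusion and match subsequent selections", {
  repo <- uterusEx$repository; kb <- uterusEx$knowledgeBase
  base <- facetCounts(repo, kb, FacetedQuery(), "original", "tissue")
  expect_identical(base[["uterus"]], 57L)
  expect_identical(base[["uterus nos"]], 1651L)
  expect_identical(base[["corpus uteri"]], 9535L)
  # selecting a tissue value leaves the tissue drop-down counts unchanged
  after <- facetCounts(repo, kb, FacetedQuery(tissue = "uterus"),
                       "original", "tissue")
  expect_identical(after, base)
  # facet-count/selection consistency: the promised count is delivered
  for (v in c("uterus", "cervix", "endometrium")) {
    expect_identical(
      length(evaluateQuery(repo, kb, FacetedQuery(tissue = v), "original")),
      base[[v]])
  }
})

test_that("key-value steps OR their predicates; sessions AND their steps", {
  repo <- tinyRepository(); kb <- KnowledgeBase()
  p1 <- KeyValuePredicate(pairs = list(clinical__status = "new tumor"),
                          exact = FALSE)
  expect_identical(itemIds(evaluateKvStep(repo, p1)), 1L)
  pExact <- KeyValuePredicate(pairs = list(clinical__status = "new tumor"),
                              exact = TRUE)
  expect_identical(length(evaluateKvStep(repo, pExact)), 0L)
  p2 <- KeyValuePredicate(pairs = list(fdr_threshold = "0.01"), exact = TRUE)
  both <- evaluateKvStep(repo, list(p1, p2))   # disjunction
  expect_identical(itemIds(both), c(1L, 3L))

  s <- QuerySession(list(FacetedQuery(tissue = "brain"), p1), "original")
  expect_identical(itemIds(evaluateSession(repo, kb, s)), 1L)
  # order independence and step removal
  s2 <- QuerySession(list(p1, FacetedQuery(tissue = "brain")), "original")
  expect_identical(itemIds(evaluateSession(repo, kb, s2)),
                   itemIds(evaluateSession(repo, kb, s)))
  expect_identical(itemIds(evaluateSession(repo, kb, removeStep(s, 2))),
                   itemIds(evaluateKvStep(repo, list(p1))))
  expect_identical(length(evaluateSession(repo, kb, QuerySession())), 4L)
})

test_that("key-value evaluation agrees with a row-scan oracle", {
  for (seed in c(3, 31)) {
    fx <- randomRepository(seed, nItems = 60)
    set.seed(seed)
    rp <- rawPairs(fx$repository)
    for (rep in 1:4) {
      exact <- sample(c(TRUE, FALSE), 1)
      keys <- sample(unique(rp$key), 2)
      pairs <- lapply(keys, function(k)
        sample(c(unique(rp$value), "zz absent"), 2))
      names(pairs) <- keys
      got <- itemIds(evaluateKvStep(
        fx$repository, KeyValuePredicate(pairs = pairs, exact = exact)))
      expect_identical(got, kvOracle(fx$repository, pairs, exact),
                       info = paste(seed, rep))
    }
  }
})

test_that("key and value search find core attributes and raw keys alike", {
  repo <- buildWorkedExample("brain")$repository
  ks <- keySearch(repo, "disease")
  expect_identical(ks$core$attribute, "disease")
  expect_identical(ks$core$n_values, 1L)   # one distinct disease value
  expect_identical(ks$raw$key, "gdc__project__disease_type")
  expect_identical(ks$raw$n_values, 1L)
  expect_identical(rawValuesForKey(repo, "gdc__project__disease_type"),
                   "brain lower grade glioma")
  none <- keySearch(repo, "zz nothing")
  expect_identical(nrow(none$core) + nrow(none$raw), 0L)

  vs <- valueSearch(repo, "glioma")
  expect_true("disease" %in% vs$core$attribute)
  expect_identical(vs$raw$key, "gdc__project__disease_type")
  # exact value search: full string required
  expect_identical(nrow(valueSearch(repo, "glioma", exact = TRUE)$raw), 0L)
})

test_that("key/value search counts equal a group-by oracle", {
  fx <- randomRepository(25, nItems = 60)
  rp <- rawPairs(fx$repository)
  ks <- keySearch(fx$repository, "curated")
  for (i in seq_len(nrow(ks$raw))) {
    k <- ks$raw$key[i]
    expect_identical(ks$raw$n_values[i],
                     length(unique(rp$value[rp$key == k & !is.na(rp$value)])))
  }
})

test_that("summarize partitions the result by source and dataset", {
  expect_identical(
    summarizeResult(tinyRepository(), ResultSet())$source,
    setNames(integer(0), character(0)))
  # a cohort split over seven datasets, mirroring a typical per-disease pull
  groups <- data.frame(n = c(45L, 52L, 60L, 85L, 55L, 50L, 54L),
                       dataset_name = sprintf("tcga chol ds %d", 1:7),
                       disease = "cholangiocarcinoma", source = "tcga")
  repo <- GenoFacet:::.groupRepository(groups, "chol")
  res <- evaluateQuery(repo, KnowledgeBase(),
                       FacetedQuery(disease = "cholangiocarcinoma"),
                       "original")
  expect_identical(length(res), 401L)
  s <- summarizeResult(repo, res)
  expect_identical(length(s$dataset), 7L)
  expect_identical(sum(s$dataset), 401L)
  expect_identical(sum(s$source), 401L)
  # random group-by check
  fx <- randomRepository(14, nItems = 50)
  res <- ResultSet(items(fx$repository)$item_id)
  s <- summarizeResult(fx$repository, res)
  expect_identical(sum(s$dataset), 50L)
  expect_identical(sum(s$source), 50L)
})

test_that("result table modes: replicated rows vs pipe-aggregated items", {
  repo <- tinyRepository()
  res <- ResultSet(1:4)
  repl <- renderResultTable(repo, res, mode = "replicated", pageSize = 100)
  expect_identical(nrow(repl), nrow(denormalizedView(repo)))
  aggr <- renderResultTable(repo, res, mode = "aggregated", pageSize = 100)
  expect_identical(nrow(aggr), 4L)
  expect_identical(
    aggr$biological_replicate_number[aggr$item_id == 1L], "1|2")
  expect_identical(
    aggr$case_study_source_id[aggr$item_id == 1L], "case1|case2")
  # pagination
  p2 <- renderResultTable(repo, res, mode = "aggregated", pageSize = 3,
                          page = 2)
  expect_identical(nrow(p2), 1L)
  expect_error(renderResultTable(repo, res, pageSize = 1001), "1000")
  # row multiplicity in replicated mode equals denormalize()
  fx <- randomRepository(18, nItems = 30)
  resAll <- ResultSet(items(fx$repository)$item_id)
  expect_identical(
    nrow(renderResultTable(fx$repository, resAll, mode = "replicated",
                           pageSize = 1000)),
    min(1000L, nrow(denormalize(fx$repository))))
})
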