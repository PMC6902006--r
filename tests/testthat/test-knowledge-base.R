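# Ontology vocabulary, synonym resolution and the depth-bounded closure.

test_that("unfoldClosure handles the trivial and the small chain cases", {
  expect_identical(nrow(unfoldClosure(NULL, 3)), 0L)
  e <- data.frame(parent = c(1L, 2L), child = c(2L, 3L))
  cl <- unfoldClosure(e, 3)
  expect_identical(cl$distance[cl$ancestor == 1 & cl$descendant == 3], 2L)
  # depth bound cuts the long pair off
  cl1 <- unfoldClosure(e, 1)
  expect_false(any(cl1$ancestor == 1 & cl1$descendant == 3))
})

test_that("the uterus subtree places endometrium two hops under uterus", {
  kb <- buildWorkedExample("uterus")$knowledgeBase
  uterus <- resolveLabel(kb, "uterus")
  endometrium <- resolveLabel(kb, "endometrium")
  cl <- termClosure(kb)
  expect_identical(
    cl$distance[cl$ancestor == uterus & cl$descendant == endometrium], 2L)
  expect_setequal(
    termDescendants(kb, uterus, 3),
    c(resolveLabel(kb, "body of uterus"),
      resolveLabel(kb, "uterine cervix"),
      resolveLabel(kb, "uterine wall"), endometrium))
  expect_identical(termDescendants(kb, endometrium, 3), integer(0))
  expect_error(termDescendants(kb, 999L, 3), "unknown term id")
})

test_that("closure equals the shortest-path oracle on random DAGs", {
  skip_if_not_installed("igraph")
  for (seed in c(1, 8, 21, 34)) {
    fx <- randomRepository(seed, nItems = 10, nTerms = 40)
    edges <- relationships(fx$knowledgeBase)
    for (d in 1:3) {
      expect_equal(unfoldClosure(edges, d), closureOracle(edges, d),
                   info = sprintf("seed %d depth %d", seed, d))
    }
  }
})

test_that("closure is monotone and idempotent in depth", {
  fx <- randomRepository(4, nItems = 10, nTerms = 35)
  edges <- relationships(fx$knowledgeBase)
  pairKey <- function(cl) paste(cl$ancestor, cl$descendant)
  for (d in 1:2) {
    expect_true(all(pairKey(unfoldClosure(edges, d)) %in%
                      pairKey(unfoldClosure(edges, d + 1L))))
  }
  # re-unfolding the closure's implied edge set at depth 1 reproduces the
  # distance-1 pairs
  cl <- unfoldClosure(edges, 3)
  implied <- data.frame(parent = cl$ancestor[cl$distance == 1],
                        child = cl$descendant[cl$distance == 1])
  again <- unfoldClosure(implied, 3)
  expect_equal(again, cl)
})

test_that("cycles are rejected with a named cycle", {
  e <- data.frame(parent = c(1L, 2L, 3L), child = c(2L, 3L, 1L))
  expect_error(unfoldClosure(e, 3), "cycle")
  expect_error(unfoldClosure(data.frame(parent = 1L, child = 1L), 3),
               "self loop")
})

test_that("resolveLabel matches preferred labels and synonyms, oracle-equal", {
  kb <- buildWorkedExample("uterus")$knowledgeBase
  expect_identical(resolveLabel(kb, "corpus uteri"),
                   resolveLabel(kb, "body of uterus"))
  expect_identical(resolveLabel(kb, "  Corpus   UTERI "),
                   resolveLabel(kb, "corpus uteri"))
  expect_identical(resolveLabel(kb, "no such label"), integer(0))
  bor <- buildWorkedExample("boris")$knowledgeBase
  expect_identical(resolveLabel(bor, "boris"), resolveLabel(bor, "ctcfl"))
  fx <- randomRepository(6, nItems = 10, nTerms = 30)
  labels <- c(vocabulary(fx$knowledgeBase)$pref_label,
              synonyms(fx$knowledgeBase)$label, "absent")
  for (lab in labels)
    expect_identical(resolveLabel(fx$knowledgeBase, lab),
                     resolveOracle(fx$knowledgeBase, lab))
})

test_that("annotateValue looks values up with normalization", {
  kb <- buildWorkedExample("uterus")$knowledgeBase
  expect_identical(annotateValue(kb, "tissue", "Uterus NOS"),
                   resolveLabel(kb, "uterus"))
  expect_true(is.na(annotateValue(kb, "tissue", "unmapped value")))
  expect_error(annotateValue(kb, "pipeline", "x"), "not semantically enriched")
  k5 <- buildWorkedExample("k562")$knowledgeBase
  expect_identical(annotateValue(k5, "cell", "k562 leukemia cells"),
                   resolveLabel(k5, "k562"))
})

test_that("the OBO reader extracts terms, synonyms and both edge kinds", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: XX:0000001", "name: Organ", "",
    "[Term]", "id: XX:0000002", "name: organ region",
    "is_a: XX:0000001 ! organ", "",
    "[Term]", "id: XX:0000003", "name: organ part",
    "synonym: \"piece of organ\" EXACT []",
    "relationship: part_of XX:0000002", "",
    "[Term]", "id: XX:0000004", "name: gone", "is_obsolete: true", "",
    "[Typedef]", "id: part_of"), obo)
  kb <- readOBO(obo)
  expect_identical(nrow(vocabulary(kb)), 3L)
  expect_identical(vocabulary(kb)$code,
                   c("XX_0000001", "XX_0000002", "XX_0000003"))
  expect_identical(resolveLabel(kb, "piece of organ"),
                   resolveLabel(kb, "organ part"))
  expect_setequal(relationships(kb)$rel_type, c("IS_A", "PART_OF"))
  expect_setequal(termDescendants(kb, resolveLabel(kb, "organ")),
                  c(resolveLabel(kb, "organ region"),
                    resolveLabel(kb, "organ part")))
})
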