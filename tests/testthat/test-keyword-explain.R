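# Keyword search across inference levels and deduction-chain explanation.

brainEx <- buildWorkedExample("brain")

test_that("keyword levels are cumulative and group by chain signature", {
  repo <- brainEx$repository; kb <- brainEx$knowledgeBase
  l1 <- keywordSearch(repo, kb, "brain", level = 1)
  expect_identical(length(l1$items), 789L + 4670L + 126L + 2463L)
  expect_identical(
    l1$chains[["<Item> - <Key: biosample__organ_slims, Value: brain>"]],
    sort(l1$chains[["<Item> - <Key: biosample__organ_slims, Value: brain>"]]))
  expect_identical(
    length(l1$chains[["<Item> - <Key: gdc__project__disease_type, Value: brain lower grade glioma>"]]),
    4670L)

  l2 <- keywordSearch(repo, kb, "brain", level = 2)
  sig2 <- "<Item> - <Replicate> - <Biosample.tissue: brain>"
  expect_identical(length(l2$chains[[sig2]]), 15714L)
  # substring matching: disease and cell values containing 'brain' match too
  expect_identical(
    length(l2$chains[["<Item> - <Replicate> - <Biosample.disease: brain lower grade glioma>"]]),
    9188L)
  expect_identical(
    length(l2$chains[["<Item> - <Replicate> - <Biosample.cell: smooth muscle cell of the brain vasculature>"]]),
    10L)

  l3 <- keywordSearch(repo, kb, "brain", level = 3)
  expect_identical(
    length(l3$chains[["<Item> - <Replicate> - <Biosample.cell: fetal brain> - <Vocabulary: brain, UBERON_0000955>"]]),
    13L)

  l4 <- keywordSearch(repo, kb, "brain", level = 4)
  ponsSig <- paste0(
    "<Item> - <Replicate> - <Biosample.tissue: pons> - ",
    "<Vocabulary: pons, UBERON_0000988> -[IS_A]- ",
    "<Vocabulary: regional part of brain, UBERON_0002616> -[PART_OF]- ",
    "<Vocabulary: brain, UBERON_0000955>")
  expect_identical(length(l4$chains[[ponsSig]]), 10L)
  gpSig <- paste0(
    "<Item> - <Replicate> - <Biosample.tissue: globus pallidus> - ",
    "<Vocabulary: globus pallidus, UBERON_0001875> -[PART_OF]- ",
    "<Vocabulary: pallidum, UBERON_0006514> -[IS_A]- ",
    "<Vocabulary: brain gray matter, UBERON_0003528> -[PART_OF]- ",
    "<Vocabulary: brain, UBERON_0000955>")
  expect_identical(length(l4$chains[[gpSig]]), 8L)

  # supersets level by level; items deduplicated in the total
  expect_true(all(l1$items %in% l2$items))
  expect_true(all(l2$items %in% l3$items))
  expect_true(all(l3$items %in% l4$items))
  expect_identical(l4$items, sort(unique(unlist(l4$chains))))

  none <- keywordSearch(repo, kb, "zz absent keyword", level = 4)
  expect_identical(length(none$chains), 0L)
  expect_identical(length(none$items), 0L)
})

test_that("explain returns exactly the chains that justify a match", {
  repo <- brainEx$repository; kb <- brainEx$knowledgeBase
  den <- denormalizedView(repo)
  pons <- den$item_id[!is.na(den$tissue) & den$tissue == "pons"][1]
  chains <- explainItem(repo, kb, pons, "brain", 4)
  expect_length(chains, 1L)
  expect_identical(chainEdges(chains[[1]]),
                   c("FK", "FK", "ANNOTATED-BY", "IS_A", "PART_OF"))
  nodes <- chainNodes(chains[[1]])
  expect_identical(nodes[[1]]$kind, "ITEM")
  expect_identical(nodes[[length(nodes)]]$label, "brain")
  # level 3 does not reach pons (needs hierarchical expansion)
  expect_length(explainItem(repo, kb, pons, "brain", 3), 0L)

  direct <- den$item_id[!is.na(den$tissue) & den$tissue == "brain"][1]
  ch2 <- explainItem(repo, kb, direct, "brain", 2)
  expect_length(ch2, 1L)
  expect_identical(chainSignature(ch2[[1]]),
                   "<Item> - <Replicate> - <Biosample.tissue: brain>")

  rawOnly <- rawPairs(repo)$item_id[rawPairs(repo)$key ==
                                      "biosample__organ_slims"][1]
  expect_length(explainItem(repo, kb, rawOnly, "brain", 1), 1L)
  expect_error(explainItem(repo, kb, 10^7, "brain", 4), "unknown item")
})

test_that("explanation completeness: matched iff explainable", {
  repo <- brainEx$repository; kb <- brainEx$knowledgeBase
  set.seed(99)
  for (L in c(1L, 2L, 4L)) {
    found <- keywordSearch(repo, kb, "brain", level = L)$items
    inside <- sample(found, 3)
    outside <- sample(setdiff(items(repo)$item_id, found),
                      min(3, itemCount(repo) - length(found)))
    for (i in inside)
      expect_gt(length(explainItem(repo, kb, i, "brain", L)), 0)
    for (i in outside)
      expect_length(explainItem(repo, kb, i, "brain", L), 0L)
  }
})
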