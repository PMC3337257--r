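# small corpus with controlled literal containment and annotations
lit_corpus <- function() {
  corpus(list(
    document("p1", "Outcomes in tricuspid atresia patients", "", "J1", 1990, "TA"),
    document("p2", "Tricuspid atresias revisited", "", "J1", 1991, "TA"),
    document("p3", "More on tricuspid atresia", "", "J2", 1992, "TA"),
    document("p4", "Unrelated cardiology topic", "", "J2", 1993, "OTHER"),
    # contains the term literally but is NOT annotated with it
    document("n1", "Imaging of tricuspid atresia anatomy", "", "J3", 1994, "FAR"),
    document("n2", "No mention at all", "tricuspid atresia discussed here",
             "J3", 1995, "NEAR"),
    # reordered, non-contiguous
    document("n3", "Atresia of the tricuspid valve", "", "J4", 1996, "FAR"),
    document("n4", "Nothing relevant", "", "J4", 1997, character())
  ))
}

lit_tree <- function() {
  mesh_tree(list(
    mesh_term("TA", "Tricuspid Atresia", tree_numbers = "A1.1.1.1"),
    mesh_term("NEAR", "Near Term", tree_numbers = "A1.1.1.2"),
    mesh_term("OTHER", "Other Term", tree_numbers = "A1.2"),
    mesh_term("A1", "Branch A1", tree_numbers = "A1"),
    mesh_term("A11", "Branch A11", tree_numbers = "A1.1"),
    mesh_term("A111", "Branch A111", tree_numbers = "A1.1.1"),
    mesh_term("B1", "Branch B1", tree_numbers = "B1"),
    mesh_term("B11", "Branch B11", tree_numbers = "B1.1"),
    mesh_term("B111", "Branch B111", tree_numbers = "B1.1.1"),
    mesh_term("FAR", "Far Term", tree_numbers = "B1.1.1.1")
  ))
}

test_that("positive selection returns all annotated docs below the cap", {
  corp <- lit_corpus()
  expect_setequal(select_positives(corp, "TA"), c("p1", "p2", "p3"))
  expect_warning(out <- select_positives(corp, "ABSENT"), "no positive")
  expect_length(out, 0)
})

test_that("positive capping is uniform, seeded and reproducible", {
  docs <- lapply(1:40, function(i)
    document(sprintf("d%02d", i), "x", "", "J", 1990, "T"))
  corp <- corpus(docs)
  s1 <- select_positives(corp, "T", cap = 10, seed = 99)
  s2 <- select_positives(corp, "T", cap = 10, seed = 99)
  s3 <- select_positives(corp, "T", cap = 10, seed = 100)
  expect_length(s1, 10)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  expect_true(all(s1 %in% names(corp$documents)))
})

test_that("literal containment requires a contiguous stemmed match", {
  term <- mesh_term("TA", "Tricuspid Atresia", tree_numbers = "A1.1.1.1")
  corp <- lit_corpus()
  expect_true(contains_term_literally(corp$documents[["p1"]], term))
  expect_true(contains_term_literally(corp$documents[["p2"]], term))  # stemmed plural
  expect_true(contains_term_literally(corp$documents[["n2"]], term))  # abstract
  expect_false(contains_term_literally(corp$documents[["n3"]], term)) # reordered
  expect_false(contains_term_literally(corp$documents[["n4"]], term))
  empty <- document("e", "zz", "", "J", 1990)
  expect_false(contains_term_literally(empty, term))
  # synonyms only when enabled
  syn <- mesh_term("S", "Completely Different", synonyms = "tricuspid atresia",
                   tree_numbers = "B1.1")
  expect_false(contains_term_literally(corp$documents[["p1"]], syn))
  expect_true(contains_term_literally(corp$documents[["p1"]], syn,
                                      use_synonyms = TRUE))
})

test_that("negative strategies build nested pools that exclude positives", {
  corp <- lit_corpus()
  tree <- lit_tree()
  term <- tree$terms[["TA"]]
  pos <- select_positives(corp, "TA")

  rnd <- select_negatives(corp, term, "random", n = 5, seed = 1, tree = tree)
  expect_length(rnd, 5)
  expect_length(intersect(rnd, pos), 0)

  # n1 (title), n2 (abstract) contain the term literally and lack the label;
  # p1..p3 are excluded as positives despite containing it
  expect_warning(
    lit <- select_negatives(corp, term, "literal", n = 10, seed = 1, tree = tree),
    "smaller than requested")
  expect_setequal(lit, c("n1", "n2"))

  # distance(TA, FAR) = 4+4-0 = 8 > 6 -> distant; distance(TA, NEAR) = 2 -> not
  dist <- select_negatives(corp, term, "literal_distant", n = 1, seed = 1,
                           tree = tree)
  expect_equal(dist, "n1")
  expect_error(select_negatives(corp, term, "literal_distant", n = 1, seed = 1),
               "requires a tree")
  # empty pool is a structured error naming term and strategy
  far <- tree$terms[["FAR"]]
  expect_error(
    suppressWarnings(select_negatives(corp, far, "literal", n = 1, seed = 1)),
    "FAR.*literal")
})

test_that("unannotated documents are skipped for literal_distant with a log entry", {
  corp <- lit_corpus()
  tree <- lit_tree()
  # make n4 contain the term literally but keep it unannotated
  docs <- corp$documents
  docs[["n4"]] <- document("n4", "tricuspid atresia notes", "", "J4", 1997)
  corp2 <- corpus(unname(docs))
  expect_warning(
    out <- select_negatives(corp2, tree$terms[["TA"]], "literal_distant",
                            n = 1, seed = 1, tree = tree),
    "unannotated")
  expect_equal(out, "n1")
})

test_that("selection is reproducible and never overlaps positives", {
  spec <- generator_spec(tree_depth = 4, branching = 2, n_docs = 400, seed = 17)
  tree <- generate_toy_tree(spec)
  corp <- generate_corpus(tree, spec)
  tids <- names(corp$term_index)[vapply(corp$term_index, length, integer(1)) >= 5]
  for (tid in tids[1:4]) {
    term <- tree$terms[[tid]]
    pos <- select_positives(corp, tid)
    for (strat in c("random", "literal", "literal_distant")) {
      n1 <- quiet(select_negatives(corp, term, strat, n = length(pos),
                                   seed = 7, tree = tree))
      n2 <- quiet(select_negatives(corp, term, strat, n = length(pos),
                                   seed = 7, tree = tree))
      expect_identical(n1, n2)
      expect_length(intersect(n1, pos), 0)
    }
    # pool nesting: literal_distant subset of literal subset of non-positives
    all_ids <- names(corp$documents)
    lit_pool <- quiet(select_negatives(corp, term, "literal",
                                       n = length(all_ids), seed = 1, tree = tree))
    dist_pool <- quiet(select_negatives(corp, term, "literal_distant",
                                        n = length(all_ids), seed = 1, tree = tree))
    expect_true(all(dist_pool %in% lit_pool))
    expect_true(all(lit_pool %in% setdiff(all_ids, pos)))
  }
})

test_that("term training sets serialize and restore exactly", {
  corp <- lit_corpus()
  tree <- lit_tree()
  tts <- quiet(term_training_set(corp, tree$terms[["TA"]], tree,
                                 strategy = "literal", seed = 3))
  expect_length(intersect(tts$positives, tts$negatives), 0)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_training_sets(list(tts), path)
  back <- read_training_sets(path)[[1]]
  expect_equal(back$term_id, tts$term_id)
  expect_equal(back$positives, tts$positives)
  expect_equal(back$negatives, tts$negatives)
  expect_equal(back$strategy, tts$strategy)
  expect_equal(back$seed, tts$seed)
})
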