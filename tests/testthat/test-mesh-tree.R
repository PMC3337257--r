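test_that("tree construction enforces structural invariants", {
  tt <- toy_tree()
  expect_length(tt$terms, 4)
  expect_length(tt$index, 4)

  # orphan parent position
  expect_error(
    mesh_tree(list(mesh_term("A", "a", tree_numbers = "A01"),
                   mesh_term("X", "x", tree_numbers = "A01.001.001"))),
    "orphan.*A01\\.001"
  )
  # duplicate tree number
  expect_error(
    mesh_tree(list(mesh_term("A", "a", tree_numbers = "A01"),
                   mesh_term("B", "b", tree_numbers = "A01"))),
    "tree number 'A01'"
  )
  expect_error(mesh_tree(list()), "empty")
  expect_error(mesh_term("Z", "   ", tree_numbers = "A01"), "label")
  expect_error(mesh_term("Z", "z", tree_numbers = character(0)), "tree numbers")
  expect_error(mesh_term("Z", "z", tree_numbers = "A01..002"), "malformed")
})

test_that("polyhierarchic terms index once per tree number", {
  tt <- mesh_tree(list(
    mesh_term("A", "a", tree_numbers = "A01"),
    mesh_term("B2", "b", tree_numbers = "B02"),
    mesh_term("B3", "b3", tree_numbers = "B02.003"),
    mesh_term("P", "p", tree_numbers = c("A01.001", "B02.003.004"))
  ))
  expect_length(tt$terms, 4)
  expect_length(tt$index, 5)
  expect_equal(unname(tt$index[["A01.001"]]), "P")
  expect_equal(unname(tt$index[["B02.003.004"]]), "P")
  expect_equal(min_depth(tt, "P"), 2)  # minimum over the two positions
})

test_that("TSV round-trip and load errors", {
  tt <- toy_tree2()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mesh_tree(tt, path)
  back <- load_mesh_tree(path)
  expect_setequal(names(back$terms), names(tt$terms))
  expect_equal(sort(names(back$index)), sort(names(tt$index)))
  expect_equal(back$terms[["B2"]]$preferred_label, "bravo deep")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term_id\tlabel\tsynonyms\ttree_numbers",
               "X\tlone leaf\t\tA01.001.001"), bad)
  expect_error(load_mesh_tree(bad), "A01\\.001")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("term_id\tlabel\tsynonyms\ttree_numbers", empty)
  expect_error(load_mesh_tree(empty), "no rows")
})

test_that("depth, common parents and distance match the worked examples", {
  tt <- toy_tree()
  expect_equal(min_depth(tt, "A"), 1)
  expect_equal(min_depth(tt, "D"), 3)
  expect_equal(common_parents(tt, "B", "C"), 1)
  expect_equal(common_parents(tt, "B", "B"), 2)
  tt2 <- toy_tree2()
  expect_equal(common_parents(tt2, "A1", "B1"), 0)
  expect_equal(min_depth(mesh_tree(list(
    mesh_term("A", "a", tree_numbers = "A01"),
    mesh_term("B2", "b", tree_numbers = "B02"),
    mesh_term("B3", "b3", tree_numbers = "B02.003"),
    mesh_term("P", "p", tree_numbers = c("A01.001", "B02.003.004"))
  )), "P"), 2)

  expect_equal(term_distance(tt, "B", "B"), 0)
  expect_equal(term_distance(tt, "B", "C"), 2)      # siblings
  expect_equal(term_distance(tt, "A", "D"), 2)      # ancestor-descendant
  expect_error(min_depth(tt, "nope"), "unknown term")
  expect_error(term_distance(tt, "A", "nope"), "unknown term")
})

test_that("term-abstract distance is the maximum over abstract terms", {
  tt2 <- toy_tree2()
  # depths: A1=2, A2=2, B1=2; CP(A1,A2)=1, CP(A1,B1)=0
  expect_equal(term_abstract_distance(tt2, "A1", c("A2", "B1")), max(2, 4))
  expect_equal(term_abstract_distance(tt2, "A1", "A1"), 0)
  expect_equal(term_abstract_distance(tt2, "A1", "B1"),
               term_distance(tt2, "A1", "B1"))
  expect_error(term_abstract_distance(tt2, "A1", character(0)), "undefined")
})

test_that("semantic distantness is a strict threshold and monotone", {
  tt2 <- toy_tree2()
  d <- term_abstract_distance(tt2, "A1", "B2")  # 2 + 3 - 0 = 5
  expect_equal(d, 5)
  expect_false(is_semantically_distant(tt2, "A1", "B2", depth_threshold = 5))
  expect_true(is_semantically_distant(tt2, "A1", "B2", depth_threshold = 4))
  expect_false(is_semantically_distant(tt2, "A1", "A1", depth_threshold = 0))
  # monotone non-increasing in the threshold
  vals <- vapply(0:8, function(th)
    is_semantically_distant(tt2, "A1", c("A2", "B2"), th), logical(1))
  expect_true(all(diff(as.integer(vals)) <= 0))
})

test_that("distance equals the BFS path oracle on monohierarchic trees", {
  skip_if_not_installed("igraph")
  spec <- generator_spec(tree_depth = 3, branching = 2, n_docs = 20, seed = 3)
  tree <- generate_toy_tree(spec)
  mono <- Filter(function(t) length(t$tree_numbers) == 1L, tree$terms)
  expect_gte(length(mono), 12)
  ids <- names(mono)
  for (t1 in ids) {
    for (t2 in ids) {
      expect_equal(term_distance(tree, t1, t2),
                   bfs_distance_oracle(tree, t1, t2),
                   info = paste(t1, t2))
    }
  }
})

test_that("distance is symmetric, non-negative, and bounded by depths", {
  spec <- generator_spec(tree_depth = 4, branching = 2, n_docs = 30, seed = 9)
  tree <- generate_toy_tree(spec)
  ids <- names(tree$terms)
  set.seed(1)
  pairs <- cbind(sample(ids, 60, replace = TRUE), sample(ids, 60, replace = TRUE))
  for (i in seq_len(nrow(pairs))) {
    t1 <- pairs[i, 1]; t2 <- pairs[i, 2]
    d12 <- term_distance(tree, t1, t2)
    expect_gte(d12, 0)
    expect_equal(d12, term_distance(tree, t2, t1))
    expect_lte(common_parents(tree, t1, t2),
               min(min_depth(tree, t1), min_depth(tree, t2)))
  }
  mono <- names(Filter(function(t) length(t$tree_numbers) == 1L, tree$terms))
  for (t in mono) expect_equal(term_distance(tree, t, t), 0)
})
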