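# Shared fixtures and independent oracles used across the suite.

# 4-term toy hierarchy from direct construction
toy_tree <- function() {
  mesh_tree(list(
    mesh_term("A", "alpha", tree_numbers = "A01"),
    mesh_term("B", "beta", tree_numbers = "A01.001"),
    mesh_term("C", "gamma", tree_numbers = "A01.002"),
    mesh_term("D", "delta", tree_numbers = "A01.001.001")
  ))
}

# two-branch tree for distance tests across branches
toy_tree2 <- function() {
  mesh_tree(list(
    mesh_term("A", "alpha", tree_numbers = "A01"),
    mesh_term("A1", "alpha one", tree_numbers = "A01.001"),
    mesh_term("A2", "alpha two", tree_numbers = "A01.002"),
    mesh_term("B", "bravo", tree_numbers = "B02"),
    mesh_term("B1", "bravo one", tree_numbers = "B02.003"),
    mesh_term("B2", "bravo deep", tree_numbers = "B02.003.004")
  ))
}

# BFS shortest-path oracle over the parent/child graph of a monohierarchic
# tree; top-level positions hang off a virtual root. Independent of the
# closed-form distance it validates.
bfs_distance_oracle <- function(tree, t1, t2) {
  skip_if_not_installed("igraph")
  tns <- names(tree$index)
  edges <- character(0)
  for (tn in tns) {
    comp <- strsplit(tn, ".", fixed = TRUE)[[1]]
    parent <- if (length(comp) == 1L) "__root__" else
      paste(comp[-length(comp)], collapse = ".")
    edges <- c(edges, parent, tn)
  }
  g <- igraph::make_graph(edges, directed = FALSE)
  n1 <- tree$terms[[t1]]$tree_numbers[1]
  n2 <- tree$terms[[t2]]$tree_numbers[1]
  as.numeric(igraph::distances(g, v = n1, to = n2))
}

# Coarse-to-fine grid maximization of the penalized two-parameter logistic
# objective (difference weight + intercept difference), independent of IRLS.
grid_search_oracle <- function(x, y, prior_variance, span = 10, rounds = 6) {
  obj <- function(wf, b) {
    eta <- wf * x + b
    sum(y * eta - log1p(exp(eta))) - wf^2 / (4 * prior_variance)
  }
  c_wf <- 0; c_b <- 0; h <- span
  for (r in seq_len(rounds)) {
    wf_grid <- seq(c_wf - h, c_wf + h, length.out = 41)
    b_grid <- seq(c_b - h, c_b + h, length.out = 41)
    vals <- outer(wf_grid, b_grid, Vectorize(obj))
    best <- arrayInd(which.max(vals), dim(vals))
    c_wf <- wf_grid[best[1]]; c_b <- b_grid[best[2]]
    h <- h / 8
  }
  c(w_feature = c_wf, w_intercept = c_b)
}

# small deterministic labeled-instance set: feature "f" mostly co-occurs with
# the positive class but not perfectly (interior optimum)
noisy_instances <- function() {
  mk <- function(feats, label, times) {
    replicate(times, list(features = feats, label = label), simplify = FALSE)
  }
  c(mk("f", 1, 6), mk(character(0), 1, 2), mk("f", 0, 1), mk(character(0), 0, 7))
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
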