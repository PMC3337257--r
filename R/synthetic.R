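#' Synthetic study specification
#'
#' Parameters of the toy-ontology and corpus generator used to exercise every
#' pipeline stage without an external corpus. The generated world mirrors the
#' statistical structure the annotator exploits: each term induces a
#' vocabulary signal in titles/abstracts (its surface token plus a small
#' term-specific co-occurring vocabulary), an optional home-journal affinity,
#' an optional publication-year trend, literal mentions of terms in documents
#' not annotated with them (so literal negative pools are non-empty), and
#' controllable ambiguity (pairs of distinct terms sharing one surface
#' string).
#'
#' The default desk-scale preset is a depth-4, branching-2 tree (30 terms)
#' with 3,000 documents; a full cross-validated pipeline run on it takes a few
#' minutes on one CPU.
#'
#' @param tree_depth Depth of the complete tree (default 4; must be >= 2).
#' @param branching Children per node (default 2; must be >= 2).
#' @param n_docs Number of documents (default 3000).
#' @param vocab_size Background (noise) vocabulary size (default 120); must be
#'   at least the number of terms.
#' @param signal_strength Probability that each term-signal token appears in a
#'   positive document's title/abstract (default 0.9).
#' @param background_rate Per-slot probability of noise tokens (default 0.3).
#' @param journal_affinity Probability a document is published in its primary
#'   term's home journal (default 0.7).
#' @param year_trend `NULL` (uniform years) or a named list mapping term ids
#'   to `c(peak_year, width)`; a document annotated with a trending term draws
#'   its year from a normal distribution centred on that term's peak,
#'   truncated to the configured range.
#' @param ambiguity_fraction Share of annotation-eligible terms arranged into
#'   cross-branch pairs sharing one surface string (default 0).
#' @param mention_rate Expected number of literal mentions of non-gold terms
#'   injected per abstract (default 2).
#' @param n_covocab Term-specific co-occurring vocabulary size (default 3).
#' @param n_journals Number of journals (default 10).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return Object of class `"generator_spec"`; `n_terms` is the implied tree
#'   size `sum(branching^(1:tree_depth))`.
#' @export
generator_spec <- function(tree_depth = 4L, branching = 2L, n_docs = 3000L,
                           vocab_size = 120L, signal_strength = 0.9,
                           background_rate = 0.3, journal_affinity = 0.7,
                           year_trend = NULL, ambiguity_fraction = 0,
                           mention_rate = 2, n_covocab = 3L,
                           n_journals = 10L, seed = 1L) {
  stopifnot(tree_depth >= 2, branching >= 2,
            signal_strength >= 0, signal_strength <= 1,
            background_rate >= 0, background_rate <= 1,
            journal_affinity >= 0, journal_affinity <= 1,
            ambiguity_fraction >= 0, ambiguity_fraction <= 1,
            mention_rate >= 0)
  n_terms <- sum(branching^seq_len(tree_depth))
  if (n_docs < n_terms) {
    meshent_stop("n_docs (%d) must be at least n_terms (%d)", n_docs, n_terms)
  }
  structure(list(tree_depth = as.integer(tree_depth),
                 branching = as.integer(branching),
                 n_terms = as.integer(n_terms),
                 n_docs = as.integer(n_docs),
                 vocab_size = as.integer(vocab_size),
                 signal_strength = signal_strength,
                 background_rate = background_rate,
                 journal_affinity = journal_affinity,
                 year_trend = year_trend,
                 ambiguity_fraction = ambiguity_fraction,
                 mention_rate = mention_rate,
                 n_covocab = as.integer(n_covocab),
                 n_journals = as.integer(n_journals),
                 seed = as.integer(seed)),
            class = "generator_spec")
}

# Synthetic tokens are vowel-free letter strings: Porter stemming is the
# identity on them and they can never collide with the stop-word list.
make_tokens <- function(n, prefix) {
  cons <- c("b", "d", "f", "g", "h", "j", "k", "l", "m", "n",
            "p", "r", "t", "v", "w", "x", "z")
  out <- character(n)
  seen <- new.env(parent = emptyenv())
  i <- 0L
  while (i < n) {
    tok <- paste0(prefix, paste(sample(cons, 5, replace = TRUE), collapse = ""))
    if (is.null(seen[[tok]])) {
      i <- i + 1L
      out[i] <- tok
      assign(tok, TRUE, envir = seen)
    }
  }
  out
}

#' Generate a toy ontology
#'
#' Builds a complete tree of the configured depth and branching with synthetic
#' single-token labels. Roughly 10% of the leaves receive a second tree number
#' under a different branch (polyhierarchy), and under a positive
#' `ambiguity_fraction` pairs of deep terms from different top-level branches
#' are given the same surface label. Deterministic under the spec seed.
#'
#' @param spec A [generator_spec()].
#' @return A [mesh_tree()].
#' @export
generate_toy_tree <- function(spec) {
  with_seed(derive_seed(spec$seed, "toy-tree"), {
    b <- spec$branching
    depth <- spec$tree_depth
    # enumerate tree numbers level by level
    levels <- list(paste0("A", seq_len(b)))
    for (d in seq_len(depth - 1L)) {
      levels[[d + 1L]] <- as.vector(vapply(levels[[d]], function(p)
        paste0(p, ".", seq_len(b)), character(b)))
    }
    tns <- unlist(levels, use.names = FALSE)
    n <- length(tns)
    labels <- make_tokens(n, "q")
    ids <- sprintf("T%03d", seq_len(n))
    tn_list <- as.list(tns)

    # polyhierarchy: ~10% of leaves get a second position under a random
    # internal node of the penultimate level, using a component index beyond
    # the regular branching so no position collides
    leaves <- which(tns %in% levels[[depth]])
    n_poly <- max(1L, floor(0.10 * length(leaves)))
    poly <- sort(sample(leaves, n_poly))
    parents <- if (depth >= 2) levels[[depth - 1L]] else levels[[1L]]
    for (k in seq_along(poly)) {
      parent <- sample(parents, 1)
      tn_list[[poly[k]]] <- c(tn_list[[poly[k]]],
                              paste0(parent, ".", b + k))
    }

    # ambiguity: pair deep terms across the two halves of the top level and
    # give each pair one shared surface string
    eligible <- annotation_terms_idx(tns, depth)
    if (spec$ambiguity_fraction > 0) {
      branch1 <- eligible[startsWith(tns[eligible], "A1")]
      branch2 <- eligible[!startsWith(tns[eligible], "A1")]
      n_pairs <- floor(spec$ambiguity_fraction * length(eligible) / 2)
      n_pairs <- min(n_pairs, length(branch1), length(branch2))
      if (n_pairs > 0) {
        p1 <- sort(sample(branch1, n_pairs))
        p2 <- sort(sample(branch2, n_pairs))
        shared <- make_tokens(n_pairs, "qq")
        labels[p1] <- shared
        labels[p2] <- shared
      }
    }
    mesh_tree(lapply(seq_len(n), function(i)
      mesh_term(ids[i], labels[i], tree_numbers = tn_list[[i]])))
  })
}

# Terms eligible for gold annotation: the two deepest levels, mirroring the
# most-specific-heading indexing convention (and making the depth-6 distance
# threshold attainable on a depth-4 tree).
annotation_terms_idx <- function(tns, depth) {
  comp_depth <- lengths(strsplit(tns, ".", fixed = TRUE))
  which(comp_depth >= max(1L, depth - 1L))
}

#' Generate a synthetic annotated corpus
#'
#' Draws `n_docs` documents, each gold-annotated with 1–3 terms from the two
#' deepest tree levels. Titles and abstracts mix per-term signal (the term's
#' surface token plus its co-occurring vocabulary, each present with
#' probability `signal_strength`) with background noise tokens; the journal
#' follows the primary term's home journal with probability
#' `journal_affinity`; years follow a gold term's trend when one is
#' configured, otherwise they are uniform over the open year range. Literal
#' mentions of random non-gold terms are injected into abstracts at
#' `mention_rate` per document. Ambiguous term pairs share their surface token
#' but differ in home journal and co-occurring vocabulary. Deterministic under
#' the spec seed.
#'
#' @param tree A [mesh_tree()] from [generate_toy_tree()].
#' @param spec The matching [generator_spec()].
#' @return A [corpus()].
#' @export
generate_corpus <- function(tree, spec) {
  ids <- names(tree$terms)
  n <- length(ids)
  if (spec$vocab_size < n) {
    meshent_stop("vocab_size (%d) smaller than the number of terms (%d)",
                 spec$vocab_size, n)
  }
  with_seed(derive_seed(spec$seed, "corpus"), {
    bg_vocab <- make_tokens(spec$vocab_size, "v")
    covocab <- lapply(seq_len(n), function(i) make_tokens(spec$n_covocab, "c"))
    names(covocab) <- ids
    journals <- paste0("journal", letters[seq_len(spec$n_journals)])
    home_journal <- stats::setNames(
      journals[(seq_len(n) * 7L) %% spec$n_journals + 1L], ids)
    surface <- vapply(tree$terms, function(t) t$preferred_label, character(1))
    tns <- vapply(tree$terms, function(t) t$tree_numbers[1], character(1))
    eligible <- ids[annotation_terms_idx(tns, spec$tree_depth)]
    lo <- 1951L; hi <- 2009L

    docs <- vector("list", spec$n_docs)
    for (i in seq_len(spec$n_docs)) {
      n_gold <- sample(1:3, 1)
      gold <- sample_ids(eligible, min(n_gold, length(eligible)))
      primary <- gold[1]

      title <- character(0)
      abstract <- character(0)
      for (g in gold) {
        if (stats::runif(1) < spec$signal_strength) {
          title <- c(title, surface[[g]])
        }
        if (stats::runif(1) < spec$signal_strength) {
          abstract <- c(abstract, surface[[g]])
        }
        cv <- covocab[[g]]
        title <- c(title, cv[stats::runif(length(cv)) < spec$signal_strength][1])
        abstract <- c(abstract, cv[stats::runif(length(cv)) < spec$signal_strength])
      }
      title <- title[!is.na(title)]
      n_bg_t <- stats::rbinom(1, 3, spec$background_rate)
      if (n_bg_t > 0) title <- c(title, sample(bg_vocab, n_bg_t, replace = TRUE))
      if (length(title) == 0L) title <- sample(bg_vocab, 1)
      n_bg_a <- stats::rbinom(1, 12, spec$background_rate)
      if (n_bg_a > 0) abstract <- c(abstract, sample(bg_vocab, n_bg_a,
                                                     replace = TRUE))
      n_mention <- stats::rpois(1, spec$mention_rate)
      if (n_mention > 0) {
        others <- setdiff(ids, gold)
        mentioned <- sample_ids(others, min(n_mention, length(others)))
        abstract <- c(abstract, unname(surface[mentioned]))
      }

      journal <- if (stats::runif(1) < spec$journal_affinity) {
        home_journal[[primary]]
      } else sample(journals, 1)

      trending <- gold[gold %in% names(spec$year_trend %||% list())]
      trend <- if (length(trending)) spec$year_trend[[trending[1]]] else NULL
      year <- if (!is.null(trend)) {
        min(max(as.integer(round(stats::rnorm(1, trend[1], trend[2]))), lo), hi)
      } else sample(lo:hi, 1)

      docs[[i]] <- document(sprintf("d%05d", i),
                            paste(sample(title), collapse = " "),
                            paste(sample(abstract), collapse = " "),
                            journal, year, gold)
    }
    corpus(docs)
  })
}
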