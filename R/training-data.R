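#' Select positive training documents for a term
#'
#' All documents gold-annotated with the term; when more than `cap` exist, a
#' uniform random subset of size `cap` is drawn under the given seed. The
#' default cap is 10,000.
#'
#' @param corp A [corpus()].
#' @param term_id Term identifier.
#' @param cap Maximum number of positives kept (default 10000).
#' @param seed Integer seed for the subsampling draw.
#' @return Sorted character vector of document ids.
#' @export
select_positives <- function(corp, term_id, cap = 10000, seed = 1L) {
  pos <- term_positives(corp, term_id)
  if (length(pos) == 0L) {
    meshent_warn("term '%s' has no positive documents", term_id)
    return(character(0))
  }
  if (length(pos) > cap) {
    pos <- with_seed(seed, sample_ids(pos, cap))
  }
  sort(pos)
}

#' Does a document contain a term literally?
#'
#' `TRUE` iff the stemmed token sequence of the term's preferred label (and,
#' optionally, of any synonym) occurs contiguously in the stemmed token
#' sequence of the title or of the abstract. Matching is case-insensitive and
#' stemmed, mirroring a tokenized phrase query.
#'
#' @param doc A [document()].
#' @param term A [mesh_term()].
#' @param use_synonyms Also try the term's synonyms (default `FALSE`).
#' @return Logical scalar.
#' @export
contains_term_literally <- function(doc, term, use_synonyms = FALSE) {
  needles <- term$preferred_label
  if (use_synonyms) needles <- c(needles, term$synonyms)
  hay <- list(tokenize_and_stem(doc$title), tokenize_and_stem(doc$abstract))
  for (needle in needles) {
    nt <- tokenize_and_stem(needle)
    if (length(nt) == 0L) next
    for (h in hay) {
      if (contains_contiguous(h, nt)) return(TRUE)
    }
  }
  FALSE
}

contains_contiguous <- function(haystack, needle) {
  n <- length(needle)
  h <- length(haystack)
  if (n == 0L || h < n) return(FALSE)
  starts <- which(haystack == needle[1])
  for (s in starts) {
    if (s + n - 1L <= h && all(haystack[s:(s + n - 1L)] == needle)) return(TRUE)
  }
  FALSE
}

#' Select negative training documents for a term
#'
#' Implements the three negative-selection strategies. The eligible pool
#' always excludes the term's positive documents; from it a uniform random
#' sample of size `min(n, pool size)` is drawn under the seed.
#'
#' * `"random"` — any document in the corpus not annotated with the term.
#' * `"literal"` — documents that contain the term literally
#'   ([contains_term_literally()]) but are not annotated with it (emulating a
#'   phrase query that excludes the heading itself).
#' * `"literal_distant"` — the subset of the literal pool whose gold MeSH
#'   annotations are semantically distant from the term
#'   ([is_semantically_distant()] at `depth_threshold`). Documents without
#'   gold annotations are skipped (their distance is undefined).
#'
#' @param corp A [corpus()].
#' @param term A [mesh_term()].
#' @param strategy One of `"random"`, `"literal"`, `"literal_distant"`.
#' @param n Number of negatives requested (normally the positive count).
#' @param seed Integer seed for the sampling draw.
#' @param tree A [mesh_tree()]; required for `"literal_distant"`.
#' @param depth_threshold Distance cut-off for `"literal_distant"` (default 6).
#' @param use_synonyms Passed to [contains_term_literally()].
#' @return Sorted character vector of document ids.
#' @export
select_negatives <- function(corp, term,
                             strategy = c("literal_distant", "literal", "random"),
                             n, seed = 1L, tree = NULL, depth_threshold = 6,
                             use_synonyms = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(n >= 1)
  positives <- term_positives(corp, term$term_id)
  pool <- setdiff(corpus_doc_ids(corp), positives)
  if (strategy %in% c("literal", "literal_distant")) {
    lit <- vapply(corp$documents[pool], contains_term_literally, logical(1),
                  term = term, use_synonyms = use_synonyms)
    pool <- pool[lit]
  }
  if (strategy == "literal_distant") {
    if (is.null(tree)) meshent_stop("strategy 'literal_distant' requires a tree")
    keep <- vapply(pool, function(id) {
      anns <- setdiff(corp$documents[[id]]$annotations, term$term_id)
      if (length(anns) == 0L) return(NA)
      is_semantically_distant(tree, term$term_id, anns, depth_threshold)
    }, logical(1))
    n_undef <- sum(is.na(keep))
    if (n_undef > 0L) {
      meshent_warn("term '%s': %d unannotated document(s) skipped for literal_distant",
                   term$term_id, n_undef)
    }
    pool <- pool[!is.na(keep) & keep]
  }
  if (length(pool) == 0L) {
    meshent_stop("empty negative pool for term '%s' under strategy '%s'",
                 term$term_id, strategy)
  }
  if (length(pool) < n) {
    meshent_warn("term '%s': negative pool (%d) smaller than requested %d under '%s'",
                 term$term_id, length(pool), n, strategy)
    n <- length(pool)
  }
  sort(with_seed(seed, sample_ids(pool, n)))
}

#' Per-term training set
#'
#' Bundles the seeded positive and negative selections of one term. The
#' negative count equals the positive count unless the eligible pool is
#' smaller, in which case the whole pool is used (a warning is emitted by
#' [select_negatives()]).
#'
#' @param corp A [corpus()].
#' @param term A [mesh_term()].
#' @param tree A [mesh_tree()] (needed for `"literal_distant"`).
#' @param strategy Negative-selection strategy.
#' @param positive_cap Cap on positives (default 10000).
#' @param depth_threshold Distance cut-off for `"literal_distant"`.
#' @param seed Integer seed; positive and negative draws use seeds derived
#'   from it and the term id.
#' @param use_synonyms Passed to [contains_term_literally()].
#' @return Object of class `"term_training_set"` with elements `term_id`,
#'   `positives`, `negatives`, `strategy`, `seed`.
#' @export
term_training_set <- function(corp, term, tree = NULL,
                              strategy = c("literal_distant", "literal", "random"),
                              positive_cap = 10000, depth_threshold = 6,
                              seed = 1L, use_synonyms = FALSE) {
  strategy <- match.arg(strategy)
  pos_seed <- derive_seed(seed, paste0(term$term_id, "/pos"))
  neg_seed <- derive_seed(seed, paste0(term$term_id, "/neg"))
  positives <- select_positives(corp, term$term_id, cap = positive_cap,
                                seed = pos_seed)
  if (length(positives) == 0L) {
    meshent_stop("term '%s' has no positives; cannot build a training set",
                 term$term_id)
  }
  negatives <- select_negatives(corp, term, strategy = strategy,
                                n = length(positives), seed = neg_seed,
                                tree = tree, depth_threshold = depth_threshold,
                                use_synonyms = use_synonyms)
  stopifnot(length(intersect(positives, negatives)) == 0L)
  structure(list(term_id = term$term_id, positives = positives,
                 negatives = negatives, strategy = strategy, seed = seed),
            class = "term_training_set")
}

#' @export
print.term_training_set <- function(x, ...) {
  cat(sprintf("<term_training_set %s: %d positives, %d negatives (%s, seed %d)>\n",
              x$term_id, length(x$positives), length(x$negatives), x$strategy,
              x$seed))
  invisible(x)
}

#' Serialize/restore term training sets as JSON Lines
#'
#' One JSON object per training set, carrying the term id, strategy, seed and
#' both document-id lists, for exact reruns.
#'
#' @param tts_list List of [term_training_set()] objects.
#' @param path File path.
#' @return `read_training_sets()` returns the list of training sets.
#' @export
write_training_sets <- function(tts_list, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (tts in tts_list) {
    writeLines(jsonlite::toJSON(
      list(term_id = tts$term_id, strategy = tts$strategy, seed = tts$seed,
           positives = as.list(tts$positives),
           negatives = as.list(tts$negatives)),
      auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_training_sets
#' @export
read_training_sets <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lapply(lines[nzchar(lines)], function(ln) {
    rec <- jsonlite::fromJSON(ln)
    structure(list(term_id = rec$term_id,
                   positives = sort(as.character(unlist(rec$positives))),
                   negatives = sort(as.character(unlist(rec$negatives))),
                   strategy = rec$strategy, seed = as.integer(rec$seed)),
              class = "term_training_set")
  })
}
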