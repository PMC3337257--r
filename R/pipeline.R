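#' Annotation pipeline configuration
#'
#' Collects the tunable parameters of the training/evaluation pipeline: the
#' decision-threshold offset `delta` (threshold `t = 0.5 + delta`), the tuning
#' grid, the validation fraction held out for tuning, the number of CV folds,
#' the negative-selection strategy, the tree-distance threshold, the cap on
#' positives, the feature namespaces used, the Gaussian prior variance of the
#' MaxEnt models, the configured publication-year range, and the master seed.
#'
#' @param delta Threshold offset in `[0, 0.4]` (default 0.1).
#' @param delta_grid Candidate offsets for [tune_delta()] (default 0.0–0.4 by
#'   0.1).
#' @param validation_fraction Held-out share for tuning (default 0.1).
#' @param folds Cross-validation folds (default 10).
#' @param negative_strategy `"literal_distant"` (default), `"literal"` or
#'   `"random"`.
#' @param depth_threshold Tree-distance cut-off (default 6).
#' @param positive_cap Cap on positive examples per term (default 10000).
#' @param feature_namespaces Namespaces used (default all four).
#' @param prior_variance Gaussian prior variance (default 1).
#' @param year_range Configured publication-year range (default 1950–2010).
#' @param seed Master integer seed; all per-term draws derive from it.
#' @return Object of class `"annotation_config"`.
#' @export
annotation_config <- function(delta = 0.1,
                              delta_grid = seq(0, 0.4, by = 0.1),
                              validation_fraction = 0.1,
                              folds = 10L,
                              negative_strategy = c("literal_distant",
                                                    "literal", "random"),
                              depth_threshold = 6,
                              positive_cap = 10000,
                              feature_namespaces = c("title", "abstract",
                                                     "journal", "year"),
                              prior_variance = 1.0,
                              year_range = c(1950L, 2010L),
                              seed = 1L) {
  stopifnot(delta >= 0, delta <= 0.4,
            validation_fraction > 0, validation_fraction < 1,
            folds >= 2)
  negative_strategy <- match.arg(negative_strategy)
  feature_namespaces <- match.arg(feature_namespaces,
                                  c("title", "abstract", "journal", "year"),
                                  several.ok = TRUE)
  structure(list(delta = delta, delta_grid = delta_grid,
                 validation_fraction = validation_fraction,
                 folds = as.integer(folds),
                 negative_strategy = negative_strategy,
                 depth_threshold = depth_threshold,
                 positive_cap = positive_cap,
                 feature_namespaces = feature_namespaces,
                 prior_variance = prior_variance,
                 year_range = as.integer(year_range),
                 seed = as.integer(seed)),
            class = "annotation_config")
}

#' Precision, recall and F-measure from counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`,
#' `F = 2PR / (P + R)`; each is defined as 0 when its denominator is 0.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Named numeric vector `precision`, `recall`, `f_measure`.
#' @export
prf <- function(tp, fp, fn) {
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f_measure = f)
}

# Precompute the feature sets of every document once per run.
feature_cache <- function(corp, use, year_range) {
  lapply(corp$documents, build_feature_set, use = use, year_range = year_range)
}

make_instances <- function(doc_ids, label, cache) {
  lapply(doc_ids, function(id) list(doc_id = id, features = cache[[id]],
                                    label = label))
}

#' Train the MaxEnt model of one term
#'
#' Builds the seeded per-term training set ([term_training_set()]), constructs
#' the labeled feature sets restricted to the configured namespaces, and fits
#' the penalized MaxEnt model. The model records the namespaces it was trained
#' with and a stable hash of the training-set composition for provenance.
#'
#' @param corp A [corpus()].
#' @param term A [mesh_term()].
#' @param tree A [mesh_tree()].
#' @param config An [annotation_config()].
#' @param cache Optional precomputed [feature_cache()]; built on demand.
#' @return A `"maxent_model"`.
#' @export
train_term_model <- function(corp, term, tree, config = annotation_config(),
                             cache = NULL) {
  if (length(term_positives(corp, term$term_id)) < 2L) {
    meshent_stop("term '%s' untrainable: fewer than 2 positive documents",
                 term$term_id)
  }
  tts <- term_training_set(corp, term, tree,
                           strategy = config$negative_strategy,
                           positive_cap = config$positive_cap,
                           depth_threshold = config$depth_threshold,
                           seed = config$seed)
  if (is.null(cache)) {
    sub <- corpus(unname(corp$documents[c(tts$positives, tts$negatives)]))
    cache <- feature_cache(sub, config$feature_namespaces, config$year_range)
  }
  instances <- c(make_instances(tts$positives, 1, cache),
                 make_instances(tts$negatives, 0, cache))
  model <- train_maxent(instances, prior_variance = config$prior_variance,
                        term_id = term$term_id)
  model$feature_namespaces <- config$feature_namespaces
  model$training_hash <- derive_seed(0, paste(c(tts$positives, "|", tts$negatives),
                                              collapse = ","))
  model
}

#' Multi-label annotation of a document
#'
#' Applies every model independently and returns the ids of the terms whose
#' classifier fires at threshold `0.5 + delta`. Decisions are independent
#' across terms, so any number of annotations can be returned.
#'
#' @param models List of `"maxent_model"` objects.
#' @param doc A [document()].
#' @param delta Threshold offset.
#' @param year_range Configured publication-year range.
#' @return Sorted character vector of term ids (possibly empty).
#' @export
annotate <- function(models, doc, delta = 0.1, year_range = c(1950L, 2010L)) {
  hits <- character(0)
  for (model in models) {
    fs <- build_feature_set(doc, use = model$feature_namespaces %||%
                              c("title", "abstract", "journal", "year"),
                            year_range = year_range)
    if (classify(model, fs, delta) == 1L) hits <- c(hits, model$term_id)
  }
  sort(hits)
}

#' Exact-matching baseline annotation
#'
#' Annotates a document with every term whose stemmed label (or synonym, if
#' enabled) occurs contiguously in the stemmed title or abstract. Needs no
#' training.
#'
#' @param doc A [document()].
#' @param terms List of [mesh_term()] objects.
#' @param use_synonyms Also match synonyms (default `FALSE`).
#' @return Sorted character vector of term ids.
#' @export
exact_match_annotate <- function(doc, terms, use_synonyms = FALSE) {
  hits <- vapply(terms, contains_term_literally, logical(1), doc = doc,
                 use_synonyms = use_synonyms)
  sort(vapply(terms[hits], function(t) t$term_id, character(1)))
}

# Stratified fold assignment: shuffle each class under the seed and deal
# instances round-robin into folds. Returns an integer vector named by doc id.
stratified_folds <- function(pos_ids, neg_ids, k, seed) {
  assign_class <- function(ids, salt) {
    ids <- with_seed(derive_seed(seed, salt), sample(sort(ids)))
    stats::setNames(rep_len(seq_len(k), length(ids)), ids)
  }
  c(assign_class(pos_ids, "pos"), assign_class(neg_ids, "neg"))
}

#' Tune the decision threshold offset on a validation split
#'
#' Holds out `validation_fraction` of the term's training set
#' (class-stratified, seeded), trains on the remainder, and returns the grid
#' value of `delta` maximizing the validation F-measure; ties break toward the
#' smaller offset.
#'
#' @inheritParams train_term_model
#' @return List with `delta` (the selected offset) and `validation_f` (named
#'   vector of F-measures over the grid).
#' @export
tune_delta <- function(corp, term, tree, config = annotation_config(),
                       cache = NULL) {
  if (length(config$delta_grid) == 0L) meshent_stop("empty delta grid")
  tts <- term_training_set(corp, term, tree,
                           strategy = config$negative_strategy,
                           positive_cap = config$positive_cap,
                           depth_threshold = config$depth_threshold,
                           seed = config$seed)
  if (is.null(cache)) {
    sub <- corpus(unname(corp$documents[c(tts$positives, tts$negatives)]))
    cache <- feature_cache(sub, config$feature_namespaces, config$year_range)
  }
  hold <- function(ids, salt) {
    n_val <- max(1L, round(config$validation_fraction * length(ids)))
    if (n_val >= length(ids)) {
      meshent_stop("term '%s': class too small for a validation split",
                   term$term_id)
    }
    with_seed(derive_seed(config$seed, paste0(term$term_id, salt)),
              sample_ids(ids, n_val))
  }
  val_pos <- hold(tts$positives, "/val+")
  val_neg <- hold(tts$negatives, "/val-")
  train_inst <- c(make_instances(setdiff(tts$positives, val_pos), 1, cache),
                  make_instances(setdiff(tts$negatives, val_neg), 0, cache))
  model <- train_maxent(train_inst, prior_variance = config$prior_variance,
                        term_id = term$term_id)
  proba_pos <- vapply(val_pos, function(id) predict_proba(model, cache[[id]]),
                      numeric(1))
  proba_neg <- vapply(val_neg, function(id) predict_proba(model, cache[[id]]),
                      numeric(1))
  fs <- vapply(config$delta_grid, function(d) {
    tp <- sum(proba_pos > 0.5 + d)
    fp <- sum(proba_neg > 0.5 + d)
    fn <- length(proba_pos) - tp
    prf(tp, fp, fn)[["f_measure"]]
  }, numeric(1))
  names(fs) <- format(config$delta_grid)
  best <- config$delta_grid[which.max(fs)]  # which.max takes the first maximum
  list(delta = best, validation_f = fs)
}

#' Per-term cross-validated evaluation
#'
#' For each term: builds its positive/negative training set once, partitions
#' it into class-stratified folds under the seed, and for each fold trains on
#' the remaining folds and classifies the held-out fold at the configured
#' threshold. True/false positives and false negatives accumulate across
#' folds into per-term precision/recall/F; the macro row is their unweighted
#' mean over terms. Terms that cannot be trained (too few positives, too few
#' instances per class, empty negative pool) are excluded and listed with the
#' reason.
#'
#' @param corp A [corpus()].
#' @param term_ids Character vector of term ids to evaluate.
#' @param tree A [mesh_tree()].
#' @param config An [annotation_config()].
#' @param method `"maxent"` (default), `"naive_bayes"` or `"exact_match"`;
#'   the baselines are evaluated on exactly the same folds.
#' @return Object of class `"eval_report"`: `per_term` data frame
#'   (`term_id`, `precision`, `recall`, `f_measure`, `tp`, `fp`, `fn`),
#'   `macro` named vector, `skipped` data frame, `method`, `config`.
#' @export
cross_validate <- function(corp, term_ids, tree, config = annotation_config(),
                           method = c("maxent", "naive_bayes", "exact_match")) {
  method <- match.arg(method)
  cache <- feature_cache(corp, config$feature_namespaces, config$year_range)
  rows <- list()
  skipped <- list()
  for (tid in sort(term_ids)) {
    term <- get_term(tree, tid)
    res <- tryCatch(
      cv_one_term(corp, term, tree, config, cache, method),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      skipped[[length(skipped) + 1L]] <- data.frame(term_id = tid, reason = res,
                                                    stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  per_term <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term_id = character(0), precision = numeric(0),
               recall = numeric(0), f_measure = numeric(0), tp = integer(0),
               fp = integer(0), fn = integer(0), stringsAsFactors = FALSE)
  macro <- if (nrow(per_term)) {
    c(precision = mean(per_term$precision), recall = mean(per_term$recall),
      f_measure = mean(per_term$f_measure))
  } else c(precision = 0, recall = 0, f_measure = 0)
  structure(list(per_term = per_term, macro = macro,
                 skipped = if (length(skipped)) do.call(rbind, skipped) else
                   data.frame(term_id = character(0), reason = character(0),
                              stringsAsFactors = FALSE),
                 method = method, config = config),
            class = "eval_report")
}

cv_one_term <- function(corp, term, tree, config, cache, method) {
  tts <- term_training_set(corp, term, tree,
                           strategy = config$negative_strategy,
                           positive_cap = config$positive_cap,
                           depth_threshold = config$depth_threshold,
                           seed = config$seed)
  if (length(tts$positives) < 2L || length(tts$negatives) < 2L) {
    meshent_stop("term '%s' untrainable: needs at least 2 documents per class",
                 term$term_id)
  }
  k <- min(config$folds, length(tts$positives), length(tts$negatives))
  fold_of <- stratified_folds(tts$positives, tts$negatives, k,
                              derive_seed(config$seed,
                                          paste0(term$term_id, "/folds")))
  labels <- stats::setNames(
    c(rep(1L, length(tts$positives)), rep(0L, length(tts$negatives))),
    c(tts$positives, tts$negatives))
  tp <- fp <- fn <- 0L
  for (f in seq_len(k)) {
    test_ids <- names(fold_of)[fold_of == f]
    train_ids <- names(fold_of)[fold_of != f]
    pred <- switch(
      method,
      maxent = {
        inst <- lapply(train_ids, function(id)
          list(features = cache[[id]], label = labels[[id]]))
        model <- train_maxent(inst, prior_variance = config$prior_variance,
                              term_id = term$term_id)
        vapply(test_ids, function(id)
          classify(model, cache[[id]], config$delta), integer(1))
      },
      naive_bayes = {
        inst <- lapply(train_ids, function(id)
          list(features = cache[[id]], label = labels[[id]]))
        model <- nb_train(inst)
        vapply(test_ids, function(id) nb_classify(model, cache[[id]]),
               integer(1))
      },
      exact_match = {
        vapply(test_ids, function(id)
          as.integer(contains_term_literally(corp$documents[[id]], term)),
          integer(1))
      }
    )
    truth <- labels[test_ids]
    tp <- tp + sum(pred == 1L & truth == 1L)
    fp <- fp + sum(pred == 1L & truth == 0L)
    fn <- fn + sum(pred == 0L & truth == 1L)
  }
  m <- prf(tp, fp, fn)
  data.frame(term_id = term$term_id, precision = m[["precision"]],
             recall = m[["recall"]], f_measure = m[["f_measure"]],
             tp = tp, fp = fp, fn = fn, stringsAsFactors = FALSE)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report (%s): %d terms, macro P %.4f / R %.4f / F %.4f; %d skipped>\n",
              x$method, nrow(x$per_term), x$macro[["precision"]],
              x$macro[["recall"]], x$macro[["f_measure"]], nrow(x$skipped)))
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' Header comment lines carry the method, the macro averages, the
#' configuration snapshot and any skipped terms; the body is one TSV row per
#' term (`term_id`, `precision`, `recall`, `f_measure`, `tp`, `fp`, `fn`).
#' Output is byte-deterministic for a given report.
#'
#' @param report An `"eval_report"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  cfg <- report$config
  hdr <- c(
    "#meshent-eval-report v1",
    sprintf("#method\t%s", report$method),
    sprintf("#macro\tprecision=%.6f\trecall=%.6f\tf_measure=%.6f",
            report$macro[["precision"]], report$macro[["recall"]],
            report$macro[["f_measure"]]),
    sprintf("#config\tdelta=%g\tfolds=%d\tstrategy=%s\tdepth_threshold=%g\tpositive_cap=%g\tfeatures=%s\tprior_variance=%g\tseed=%d",
            cfg$delta, cfg$folds, cfg$negative_strategy, cfg$depth_threshold,
            cfg$positive_cap, paste(cfg$feature_namespaces, collapse = ","),
            cfg$prior_variance, cfg$seed),
    sprintf("#skipped\t%s\t%s", report$skipped$term_id, report$skipped$reason)
  )
  body <- c(
    "term_id\tprecision\trecall\tf_measure\ttp\tfp\tfn",
    sprintf("%s\t%.6f\t%.6f\t%.6f\t%d\t%d\t%d",
            report$per_term$term_id, report$per_term$precision,
            report$per_term$recall, report$per_term$f_measure,
            report$per_term$tp, report$per_term$fp, report$per_term$fn)
  )
  writeLines(c(hdr, body), path, useBytes = TRUE)
  invisible(path)
}
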