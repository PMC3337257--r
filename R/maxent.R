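#' Per-term maximum-entropy classifier
#'
#' The context model of one MeSH term is a two-class conditional exponential
#' model over binary labeled features: class `c` scores
#' `s_c = intercept_c + sum of weights_c over the features present`, and
#' `p(positive) = exp(s1) / (exp(s1) + exp(s0))`. A zero-mean Gaussian prior
#' with variance `prior_variance` penalizes all feature weights (intercepts
#' are not penalized). Because the likelihood depends only on the weight
#' difference while the prior is minimized at class-symmetric weights, the
#' penalized optimum satisfies `beta1 = -beta0`; training therefore runs
#' Newton/IRLS on the difference vector and stores the symmetric split. The
#' model is exactly a penalized binary logistic regression with ridge
#' coefficient `1/(4 * prior_variance)` on the difference weights.
#'
#' @name maxent
NULL

new_maxent_model <- function(term_id, vocab, w_half, prior_variance,
                             converged, n_iter, objective_trace,
                             feature_namespaces = NULL, training_hash = NULL) {
  structure(
    list(term_id = term_id,
         feature_vocabulary = vocab,
         weights_pos = w_half,      # beta_1: per-feature weights, intercept last
         weights_neg = -w_half,     # beta_0
         prior_variance = prior_variance,
         converged = converged,
         n_iterations = n_iter,
         objective_trace = objective_trace,
         feature_namespaces = feature_namespaces,
         training_hash = training_hash),
    class = "maxent_model"
  )
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model %s: %d features, %s in %d iterations>\n",
              x$term_id %||% "?", length(x$feature_vocabulary),
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

# Build a sparse binary design matrix (n x (p+1), intercept column last) from
# a list of feature-string vectors against a fixed vocabulary.
design_matrix <- function(feature_sets, vocab) {
  n <- length(feature_sets)
  p <- length(vocab)
  idx <- lapply(feature_sets, function(f) {
    j <- match(f, vocab)
    j[!is.na(j)]
  })
  ii <- rep.int(seq_len(n), lengths(idx))
  jj <- unlist(idx, use.names = FALSE)
  Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, rep.int(p + 1L, n)),
                       x = 1, dims = c(n, p + 1L))
}

penalized_loglik <- function(w, X, y, pen_mask, pen) {
  eta <- as.numeric(X %*% w)
  # log-likelihood of the logistic model, numerically stable
  ll <- sum(y * eta - log1p(exp(pmin(eta, 35))) - pmax(eta - 35, 0))
  ll - pen * sum(w[pen_mask]^2)
}

#' Train a per-term MaxEnt model
#'
#' Maximizes the Gaussian-prior-penalized conditional log-likelihood of the
#' two-class model by Newton/IRLS iterations with step halving (the penalized
#' objective is non-decreasing across iterations). Convergence is declared
#' when the relative change of the penalized objective falls below `tol`.
#'
#' @param instances List of training instances, each a list with elements
#'   `features` (character vector of namespaced feature strings) and `label`
#'   (0 or 1). Both classes must be present.
#' @param prior_variance Variance of the zero-mean Gaussian prior on the
#'   per-class feature weights (default 1). Intercepts are unpenalized.
#' @param max_iter Maximum Newton iterations (default 100).
#' @param tol Relative objective-change tolerance (default 1e-6).
#' @param term_id Optional term identifier recorded in the model.
#' @return An object of class `"maxent_model"`.
#' @export
train_maxent <- function(instances, prior_variance = 1.0, max_iter = 100,
                         tol = 1e-6, term_id = NA_character_) {
  if (length(instances) == 0L) meshent_stop("no training instances")
  y <- vapply(instances, function(z) as.numeric(z$label), numeric(1))
  if (!all(y %in% c(0, 1))) meshent_stop("labels must be 0 or 1")
  if (length(unique(y)) < 2L) {
    meshent_stop("training requires both classes (term '%s')", term_id)
  }
  feature_sets <- lapply(instances, function(z) z$features)
  vocab <- sort(unique(unlist(feature_sets, use.names = FALSE)))
  X <- design_matrix(feature_sets, vocab)
  p <- length(vocab)
  pen_mask <- c(rep(TRUE, p), FALSE)  # intercept (last) unpenalized
  # prior (|b1|^2 + |b0|^2) / (2 s2) at b1 = -b0 = w/2  =>  |w|^2 / (4 s2)
  pen <- 1 / (4 * prior_variance)

  w <- numeric(p + 1L)
  obj <- penalized_loglik(w, X, y, pen_mask, pen)
  trace <- obj
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    mu <- stats::plogis(as.numeric(X %*% w))
    grad <- as.numeric(Matrix::crossprod(X, y - mu))
    grad[pen_mask] <- grad[pen_mask] - 2 * pen * w[pen_mask]
    s <- pmax(mu * (1 - mu), 1e-10)
    H <- as.matrix(Matrix::crossprod(X * sqrt(s)))
    diag(H)[pen_mask] <- diag(H)[pen_mask] + 2 * pen
    step <- tryCatch(solve(H, grad), error = function(e) {
      solve(H + diag(1e-8, nrow(H)), grad)
    })
    # step halving guarantees a monotone objective
    alpha <- 1
    repeat {
      w_new <- w + alpha * step
      obj_new <- penalized_loglik(w_new, X, y, pen_mask, pen)
      if (is.finite(obj_new) && obj_new >= obj - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-8) { w_new <- w; obj_new <- obj; break }
    }
    trace <- c(trace, obj_new)
    rel <- abs(obj_new - obj) / (abs(obj) + 1e-10)
    w <- w_new
    obj <- obj_new
    if (!is.finite(obj)) meshent_stop("non-finite training objective")
    if (rel < tol) { converged <- TRUE; break }
  }
  if (any(!is.finite(w))) meshent_stop("non-finite weights after training")
  new_maxent_model(term_id, vocab, w / 2, prior_variance, converged, it, trace)
}

#' Positive-class probability of a feature set
#'
#' Features absent from the model vocabulary are ignored. The probabilities of
#' the two classes sum to one; `predict_proba` returns the positive one.
#'
#' @param model A `"maxent_model"`.
#' @param features Character vector of namespaced feature strings.
#' @return Probability in `[0, 1]`.
#' @export
predict_proba <- function(model, features) {
  j <- match(features, model$feature_vocabulary)
  j <- j[!is.na(j)]
  p1 <- length(model$feature_vocabulary) + 1L
  s1 <- model$weights_pos[p1] + sum(model$weights_pos[j])
  s0 <- model$weights_neg[p1] + sum(model$weights_neg[j])
  stats::plogis(s1 - s0)
}

#' Thresholded class decision
#'
#' Returns 1 iff the positive-class probability strictly exceeds
#' `t = 0.5 + delta`.
#'
#' @inheritParams predict_proba
#' @param delta Threshold offset in `[0, 0.5]`.
#' @return 0 or 1.
#' @export
classify <- function(model, features, delta = 0.1) {
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0 || delta > 0.5) {
    meshent_stop("delta must be a number in [0, 0.5], got %s", deparse(delta))
  }
  as.integer(predict_proba(model, features) > 0.5 + delta)
}

#' Ranked positive and negative features of a model
#'
#' Ranks features by the weight difference `beta1 - beta0`: descending for the
#' positive list, ascending for the negative list, ties broken
#' lexicographically by feature string.
#'
#' @param model A `"maxent_model"`.
#' @param k Number of features per list.
#' @return List with character vectors `positive` and `negative`.
#' @export
ranked_features <- function(model, k) {
  stopifnot(k >= 1)
  p <- length(model$feature_vocabulary)
  diff <- model$weights_pos[seq_len(p)] - model$weights_neg[seq_len(p)]
  ord_pos <- order(-diff, model$feature_vocabulary)
  ord_neg <- order(diff, model$feature_vocabulary)
  k <- min(k, p)
  list(positive = model$feature_vocabulary[ord_pos][seq_len(k)],
       negative = model$feature_vocabulary[ord_neg][seq_len(k)])
}

#' Persist a MaxEnt model as a diffable text file
#'
#' One file per term: a versioned header with metadata, then one
#' `feature<TAB>beta1<TAB>beta0` line per vocabulary entry and a final
#' `__intercept__` line. `read_maxent_model()` restores the model.
#'
#' @param model A `"maxent_model"`.
#' @param path Output path.
#' @return `path` invisibly; `read_maxent_model()` returns the model.
#' @export
write_maxent_model <- function(model, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("#meshent-maxent-model v1",
               sprintf("#term_id\t%s", model$term_id),
               sprintf("#prior_variance\t%.17g", model$prior_variance),
               sprintf("#converged\t%d", as.integer(isTRUE(model$converged))),
               sprintf("#n_iterations\t%d", model$n_iterations),
               sprintf("#feature_namespaces\t%s",
                       paste(model$feature_namespaces %||% character(0),
                             collapse = ","))), con)
  p <- length(model$feature_vocabulary)
  writeLines(sprintf("%s\t%.17g\t%.17g", model$feature_vocabulary,
                     model$weights_pos[seq_len(p)],
                     model$weights_neg[seq_len(p)]), con)
  writeLines(sprintf("__intercept__\t%.17g\t%.17g",
                     model$weights_pos[p + 1L], model$weights_neg[p + 1L]), con)
  invisible(path)
}

#' @rdname write_maxent_model
#' @export
read_maxent_model <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!identical(lines[1], "#meshent-maxent-model v1")) {
    meshent_stop("'%s' is not a meshent model file", path)
  }
  meta <- lines[startsWith(lines, "#")][-1]
  kv <- strsplit(meta, "\t", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, function(x) x[2] %||% "", character(1)),
                          vapply(kv, function(x) sub("^#", "", x[1]), character(1)))
  body <- strsplit(lines[!startsWith(lines, "#")], "\t", fixed = TRUE)
  feat <- vapply(body, `[`, character(1), 1)
  b1 <- as.numeric(vapply(body, `[`, character(1), 2))
  b0 <- as.numeric(vapply(body, `[`, character(1), 3))
  stopifnot(feat[length(feat)] == "__intercept__")
  vocab <- feat[-length(feat)]
  ns <- meta[["feature_namespaces"]]
  new_maxent_model(
    term_id = meta[["term_id"]],
    vocab = vocab,
    w_half = b1,
    prior_variance = as.numeric(meta[["prior_variance"]]),
    converged = meta[["converged"]] == "1",
    n_iter = as.integer(meta[["n_iterations"]]),
    objective_trace = NULL,
    feature_namespaces = if (nzchar(ns)) strsplit(ns, ",", fixed = TRUE)[[1]]
  )
}
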