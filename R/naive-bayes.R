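#' Bernoulli naive Bayes baseline
#'
#' The comparison classifier trained on the same labeled binary features and
#' the same splits as the MaxEnt models. Per-class Bernoulli feature
#' probabilities use add-one (Laplace) smoothing,
#' `p(f = 1 | c) = (count + 1) / (n_c + 2)`; the class prior is the empirical
#' class frequency; the decision is the maximum posterior (ties go to the
#' negative class).
#'
#' @param instances Training instances as for [train_maxent()]; both classes
#'   must be present.
#' @return Object of class `"nb_model"`.
#' @export
nb_train <- function(instances) {
  y <- vapply(instances, function(z) as.numeric(z$label), numeric(1))
  if (length(unique(y)) < 2L) {
    meshent_stop("naive Bayes training requires both classes")
  }
  feature_sets <- lapply(instances, function(z) z$features)
  vocab <- sort(unique(unlist(feature_sets, use.names = FALSE)))
  count_class <- function(cls) {
    tab <- table(factor(unlist(feature_sets[y == cls], use.names = FALSE),
                        levels = vocab))
    as.numeric(tab)
  }
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  p1 <- (count_class(1) + 1) / (n1 + 2)
  p0 <- (count_class(0) + 1) / (n0 + 2)
  structure(
    list(vocab = vocab,
         log_prior = c(neg = log(n0 / (n0 + n1)), pos = log(n1 / (n0 + n1))),
         # decision weights: presence log-odds and the all-absent base score
         w_pos = log(p1 / (1 - p1)), w_neg = log(p0 / (1 - p0)),
         base_pos = sum(log(1 - p1)), base_neg = sum(log(1 - p0))),
    class = "nb_model"
  )
}

#' @rdname nb_train
#' @param model An `"nb_model"`.
#' @param features Character vector of namespaced feature strings; features
#'   outside the training vocabulary are ignored.
#' @return `nb_posterior()` returns the positive-class posterior probability;
#'   `nb_classify()` returns 0 or 1.
#' @export
nb_posterior <- function(model, features) {
  j <- match(features, model$vocab)
  j <- j[!is.na(j)]
  s1 <- model$log_prior[["pos"]] + model$base_pos + sum(model$w_pos[j])
  s0 <- model$log_prior[["neg"]] + model$base_neg + sum(model$w_neg[j])
  stats::plogis(s1 - s0)
}

#' @rdname nb_train
#' @export
nb_classify <- function(model, features) {
  as.integer(nb_posterior(model, features) > 0.5)
}
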