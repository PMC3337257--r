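test_that("separable one-feature data yields a positive weight difference", {
  inst <- c(replicate(8, list(features = "title:x", label = 1), simplify = FALSE),
            replicate(8, list(features = character(0), label = 0), simplify = FALSE))
  m <- train_maxent(inst)
  expect_true(m$converged)
  p <- length(m$feature_vocabulary)
  expect_gt(m$weights_pos[1] - m$weights_neg[1], 0)
  # perfect training classification at t = 0.5
  expect_equal(classify(m, "title:x", 0), 1L)
  expect_equal(classify(m, character(0), 0), 0L)
  expect_length(m$weights_pos, p + 1)
  expect_true(all(is.finite(c(m$weights_pos, m$weights_neg))))
})

test_that("training rejects degenerate inputs", {
  one_class <- replicate(5, list(features = "f", label = 1), simplify = FALSE)
  expect_error(train_maxent(one_class), "both classes")
  expect_error(train_maxent(list()), "no training instances")
  expect_error(train_maxent(list(list(features = "f", label = 2),
                                 list(features = "g", label = 0))),
               "labels")
})

test_that("IRLS optimum matches an independent grid search", {
  inst <- noisy_instances()
  for (sigma2 in c(0.5, 1, 4)) {
    m <- train_maxent(inst, prior_variance = sigma2)
    x <- vapply(inst, function(z) as.numeric("f" %in% z$features), numeric(1))
    y <- vapply(inst, function(z) z$label, numeric(1))
    oracle <- grid_search_oracle(x, y, sigma2)
    w_feat <- m$weights_pos[1] - m$weights_neg[1]
    w_int <- m$weights_pos[2] - m$weights_neg[2]
    expect_lt(abs(w_feat - oracle[["w_feature"]]), 1e-3)
    expect_lt(abs(w_int - oracle[["w_intercept"]]), 1e-3)
  }
})

test_that("penalized objective is non-decreasing across iterations", {
  m <- train_maxent(noisy_instances())
  expect_true(all(diff(m$objective_trace) >= -1e-9))
})

test_that("predictions agree with an independent penalized logistic fit", {
  set.seed(4)
  feats <- c("title:a", "title:b", "abstract:c")
  inst <- lapply(1:40, function(i) {
    f <- feats[runif(3) < 0.5]
    list(features = f,
         label = as.integer(runif(1) < stats::plogis(2 * ("title:a" %in% f) -
                                                       1.5 * ("title:b" %in% f))))
  })
  if (length(unique(vapply(inst, `[[`, numeric(1), "label"))) < 2) skip("degenerate draw")
  sigma2 <- 1
  m <- train_maxent(inst, prior_variance = sigma2, tol = 1e-12)
  vocab <- m$feature_vocabulary
  X <- t(vapply(inst, function(z) as.numeric(vocab %in% z$features),
                numeric(length(vocab))))
  y <- vapply(inst, `[[`, numeric(1), "label")
  negobj <- function(w) {
    eta <- as.numeric(X %*% w[-length(w)]) + w[length(w)]
    -(sum(y * eta - log1p(exp(eta))) - sum(w[-length(w)]^2) / (4 * sigma2))
  }
  fit <- optim(rep(0, length(vocab) + 1), negobj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  w_ref <- fit$par
  for (i in seq_len(20)) {
    f <- feats[runif(3) < 0.5]
    eta_ref <- sum(w_ref[match(f, vocab)]) + w_ref[length(w_ref)]
    expect_lt(abs(predict_proba(m, f) - stats::plogis(eta_ref)), 1e-6)
  }
})

test_that("class probabilities are complementary and unseen features ignored", {
  m <- train_maxent(noisy_instances())
  fsets <- list(character(0), "f", c("f", "title:never_seen"), "title:never_seen")
  for (fs in fsets) {
    p1 <- predict_proba(m, fs)
    # negative-class probability via the mirrored model
    mm <- m
    mm$weights_pos <- m$weights_neg
    mm$weights_neg <- m$weights_pos
    expect_lt(abs(p1 + predict_proba(mm, fs) - 1), 1e-12)
  }
  expect_equal(predict_proba(m, "title:never_seen"),
               predict_proba(m, character(0)))
  # all-zero weights give exactly 0.5
  m0 <- m
  m0$weights_pos[] <- 0
  m0$weights_neg[] <- 0
  expect_equal(predict_proba(m0, "f"), 0.5)
})

test_that("instance order does not change the fitted weights", {
  inst <- noisy_instances()
  m1 <- train_maxent(inst, tol = 1e-10)
  m2 <- train_maxent(rev(inst), tol = 1e-10)
  expect_lt(max(abs(m1$weights_pos - m2$weights_pos)), 1e-8)
})

test_that("instance duplication with halved prior variance preserves probabilities", {
  inst <- noisy_instances()
  m1 <- train_maxent(inst, prior_variance = 1, tol = 1e-12)
  m2 <- train_maxent(c(inst, inst), prior_variance = 0.5, tol = 1e-12)
  for (fs in list(character(0), "f")) {
    expect_lt(abs(predict_proba(m1, fs) - predict_proba(m2, fs)), 1e-6)
  }
  # duplication alone never flips the argmax class at t = 0.5
  m3 <- train_maxent(c(inst, inst), prior_variance = 1, tol = 1e-12)
  for (fs in list(character(0), "f")) {
    expect_equal(classify(m3, fs, 0), classify(m1, fs, 0))
  }
})

test_that("classification threshold is strict at t = 0.5 + delta", {
  m <- train_maxent(noisy_instances())
  # synthesize exact probabilities through a stub model with one feature
  stub <- m
  stub$feature_vocabulary <- "f"
  stub$weights_pos <- c(0, qlogis(0.61) / 2)
  stub$weights_neg <- -stub$weights_pos
  expect_equal(predict_proba(stub, character(0)), 0.61)
  expect_equal(classify(stub, character(0), 0.1), 1L)
  stub$weights_pos <- c(0, qlogis(0.60) / 2)
  stub$weights_neg <- -stub$weights_pos
  expect_equal(classify(stub, character(0), 0.1), 0L)  # boundary, strict
  expect_error(classify(m, "f", -0.1), "delta")
  expect_error(classify(m, "f", 0.6), "delta")
})

test_that("ranked features order by weight difference with lexical ties", {
  inst <- c(replicate(6, list(features = "title:x", label = 1), simplify = FALSE),
            replicate(6, list(features = "title:y", label = 0), simplify = FALSE))
  m <- train_maxent(inst)
  r <- ranked_features(m, 1)
  expect_equal(r$positive, "title:x")
  expect_equal(r$negative, "title:y")
  # k larger than vocabulary truncates to the full list
  r2 <- ranked_features(m, 100)
  expect_length(r2$positive, length(m$feature_vocabulary))
  expect_setequal(r2$positive, r2$negative)
})

test_that("model text persistence round-trips", {
  m <- train_maxent(noisy_instances(), term_id = "T42")
  m$feature_namespaces <- c("title", "year")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_maxent_model(m, path)
  expect_equal(readLines(path)[1], "#meshent-maxent-model v1")
  back <- read_maxent_model(path)
  expect_equal(back$term_id, "T42")
  expect_equal(back$feature_vocabulary, m$feature_vocabulary)
  expect_equal(back$weights_pos, m$weights_pos, tolerance = 1e-15)
  expect_equal(back$weights_neg, m$weights_neg, tolerance = 1e-15)
  expect_equal(back$feature_namespaces, c("title", "year"))
  for (fs in list(character(0), "f")) {
    expect_equal(predict_proba(back, fs), predict_proba(m, fs))
  }
})
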