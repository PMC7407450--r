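test_that("feature weights follow point-biserial correlation arithmetic", {
  set.seed(2)
  n <- 400
  y <- rep(c(1L, 0L), each = n / 2)
  x <- cbind(exact = as.numeric(y),        # correlation 1
             half = ifelse(runif(n) < 0.75, y, 1 - y), # positive, weaker
             none = rnorm(n))              # ~0
  w <- feature_weights(x, y)
  expect_equal(sum(w), 1)
  expect_true(w["exact"] > w["half"] & w["half"] > w["none"])
  # the computed weights are the normalized |cor|
  raw <- pmax(abs(apply(x, 2, function(col) cor(col, y))), 1e-6)
  expect_equal(unname(w), unname(raw / sum(raw)), tolerance = 1e-12)
  # a constant feature gets the floor weight
  w2 <- feature_weights(cbind(x, flat = rep(1, n)), y)
  expect_equal(unname(w2["flat"]) * sum(pmax(abs(c(raw[1:3], 0)), 1e-6)), 1e-6,
               tolerance = 1e-9)
})

test_that("every learner separates linearly separable toy data", {
  set.seed(8)
  n <- 60
  y <- rep(c(1L, 0L), each = n / 2)
  x <- cbind(signal = y + 0, noise1 = rnorm(n), noise2 = rnorm(n))
  for (m in c("wrf", "gbt", "nb", "knn")) {
    spec <- classifier_spec(m, n_trees = 200, nrounds = 30, seed = 5)
    fit <- fit_classifier(spec, x, y)
    s <- predict_classifier(fit, x)
    expect_true(all(s >= 0 & s <= 1), info = m)
    expect_equal(auc(s, y), 1, info = m)
  }
})

test_that("stochastic learners are reproducible under a seed", {
  co <- small_signal_cohort(n = 120, p = 40, seed = 3)
  x <- build_features(co$genotypes, co$samples, include_covariates = TRUE)
  y <- co$samples$phenotype
  for (m in c("wrf", "gbt")) {
    spec <- classifier_spec(m, n_trees = 150, nrounds = 40, seed = 77)
    s1 <- predict_classifier(fit_classifier(spec, x, y), x)
    s2 <- predict_classifier(fit_classifier(spec, x, y), x)
    expect_identical(s1, s2, info = m)
  }
})

test_that("kNN scores equal a hand-counted neighbour vote", {
  train <- cbind(f1 = c(0, 0, 0, 1, 1, 1, 0.4), f2 = c(0, 0.1, -0.1, 1, 0.9, 1.1, 0.6))
  y <- c(0L, 0L, 0L, 1L, 1L, 1L, 1L)
  test <- cbind(f1 = c(0.05, 0.95), f2 = c(0, 1))
  spec <- classifier_spec("knn", k_neighbors = 3)
  fit <- fit_classifier(spec, rbind(train, train[1:3, ] + 5), c(y, 0L, 0L, 0L))
  # brute-force neighbour search on the standardized training block
  tr <- fit$model$train
  te <- scale(test, center = fit$model$center, scale = fit$model$scale)
  hand <- apply(te, 1, function(z) {
    d <- sqrt(colSums((t(tr) - z)^2))
    mean(as.integer(as.character(fit$model$y))[order(d)[1:3]])
  })
  got <- predict_classifier(fit, test)
  expect_equal(unname(got), unname(hand))
})

test_that("naive Bayes is indifferent when class densities coincide", {
  # identical feature distributions in both classes, balanced prior
  x <- cbind(f1 = rep(c(0, 1, 2, 0, 1, 2), 10))
  y <- rep(c(1L, 0L), each = 30)
  spec <- classifier_spec("nb", laplace = 0)
  fit <- fit_classifier(spec, x, y)
  s <- predict_classifier(fit, cbind(f1 = c(0, 1, 2)))
  expect_equal(s, rep(0.5, 3), tolerance = 1e-9)
})

test_that("uniform weights make the weighted forest an ordinary forest", {
  co <- small_signal_cohort(n = 150, p = 60, seed = 13)
  x <- build_features(co$genotypes, co$samples, include_covariates = TRUE)
  y <- co$samples$phenotype
  wrf <- fit_classifier(classifier_spec("wrf", n_trees = 300, seed = 6,
                                        uniform_weights = TRUE), x, y)
  rf <- ranger::ranger(y = factor(y, levels = c(0, 1)), x = as.data.frame(x),
                       num.trees = 300, mtry = floor(sqrt(ncol(x))),
                       probability = TRUE, seed = 6, num.threads = 1)
  s_wrf <- predict_classifier(wrf, x)
  s_rf <- predict(rf, data = as.data.frame(x), num.threads = 1)$predictions[, "1"]
  expect_lt(abs(auc(s_wrf, y) - auc(s_rf, y)), 0.03)
})

test_that("layout mismatches and degenerate labels are refused", {
  x <- cbind(a = rnorm(30), b = rnorm(30))
  y <- rep(c(1L, 0L), 15)
  fit <- fit_classifier(classifier_spec("knn"), x, y)
  xx <- x; colnames(xx) <- c("b", "a")
  expect_error(predict_classifier(fit, xx), "layout mismatch")
  expect_error(fit_classifier(classifier_spec("nb"), x, rep(1L, 30)), "both classes")
})
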