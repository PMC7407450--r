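test_that("intercept-only fit recovers the case fraction through the link", {
  y <- rep(c(1L, 0L), c(150, 350))
  fit <- bayes_probit(NULL, y, model = "BRR", n_iter = 4000, burn_in = 500,
                      thin = 2, seed = 4)
  expect_lt(abs(pnorm(fit$coefficients$intercept) - 0.30), 0.02)
  # predictions are the constant baseline probability
  expect_equal(length(unique(round(fit$fitted, 10))), 1)
})

test_that("single-SNP posterior mean matches 2-D quadrature", {
  set.seed(60)
  n <- 60
  g <- matrix(rbinom(n, 2, 0.4), ncol = 1, dimnames = list(NULL, "s1"))
  eta <- -0.3 + 0.8 * (g[, 1] - mean(g[, 1]))
  y <- rbinom(n, 1, pnorm(eta))
  v0 <- 0.25
  fit <- bayes_probit(g, y, model = "BRR", n_iter = 12000, burn_in = 2000,
                      thin = 2, seed = 7, fixed_marker_var = v0)
  qo <- oracle_probit_quadrature(g[, 1] - mean(g[, 1]), y, v0)
  expect_lt(abs(fit$coefficients$markers[["s1"]] - qo$alpha_mean), 0.05)
  expect_lt(abs(fit$coefficients$intercept - qo$mu_mean), 0.05)
})

test_that("chains are reproducible under a seed and link limits hold", {
  set.seed(5)
  g <- matrix(rbinom(200, 2, 0.3), 50, 4, dimnames = list(NULL, paste0("s", 1:4)))
  y <- rbinom(50, 1, 0.5)
  f1 <- bayes_probit(g, y, model = "BayesB", n_iter = 600, burn_in = 100, seed = 9)
  f2 <- bayes_probit(g, y, model = "BayesB", n_iter = 600, burn_in = 100, seed = 9)
  expect_identical(coef(f1), coef(f2))
  expect_false(identical(
    coef(bayes_probit(g, y, model = "BayesB", n_iter = 600, burn_in = 100, seed = 10)),
    coef(f1)))
  # probabilities live strictly inside (0, 1) and follow the probit link
  eta <- predict(f1, g, type = "link")
  expect_equal(predict(f1, g), pnorm(eta))
  expect_true(all(f1$fitted > 0 & f1$fitted < 1))
  expect_error(bayes_probit(g, rep(1L, 50)), "both classes")
  gx <- g; colnames(gx) <- paste0("z", 1:4)
  expect_error(predict(f1, gx), "SNP mismatch")
})

test_that("ridge shrinkage is monotone in the prior variance", {
  set.seed(33)
  n <- 120
  g <- matrix(rbinom(n * 5, 2, 0.4), n, 5, dimnames = list(NULL, paste0("s", 1:5)))
  eta <- 0.7 * scale(g[, 2], scale = FALSE)
  y <- rbinom(n, 1, pnorm(eta))
  norms <- sapply(c(0.5, 0.05, 0.005, 5e-4), function(v) {
    f <- bayes_probit(g, y, model = "BRR", n_iter = 2500, burn_in = 500,
                      seed = 11, fixed_marker_var = v)
    sum(abs(f$coefficients$markers))
  })
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[4], 0.05) # vanishing prior variance kills all effects
})

test_that("mixture models shrink inclusion under null data", {
  set.seed(44)
  g <- matrix(rbinom(400 * 200, 2, 0.35), 400, 200,
              dimnames = list(NULL, sprintf("s%03d", 1:200)))
  y <- rbinom(400, 1, 0.4)
  f <- bayes_probit(g, y, model = "BayesCpi", n_iter = 1500, burn_in = 300,
                    seed = 13)
  expect_lt(mean(f$inclusion_prob), 0.5)
})

test_that("plug-in and posterior-averaged probabilities agree in rank", {
  co <- small_signal_cohort(n = 150, p = 80, seed = 19)
  f <- bayes_probit(co$genotypes, co$samples$phenotype,
                    covariates = covariate_matrix(co$samples),
                    model = "BRR", n_iter = 2000, burn_in = 400, seed = 3)
  expect_gt(cor(f$fitted, f$fitted_bayes, method = "spearman"), 0.99)
})

test_that("all five alphabet members fit and produce sane posteriors", {
  co <- small_signal_cohort(n = 120, p = 60, seed = 23)
  y <- co$samples$phenotype
  for (m in c("BRR", "BL", "BayesA", "BayesB", "BayesCpi")) {
    f <- bayes_probit(co$genotypes, y, model = m, n_iter = 800, burn_in = 200,
                      seed = 2)
    expect_true(all(is.finite(coef(f))), info = m)
    expect_true(all(f$fitted > 0 & f$fitted < 1), info = m)
    if (m %in% c("BayesB", "BayesCpi")) {
      expect_true(f$pi_mean > 0 && f$pi_mean < 1, info = m)
      expect_true(all(f$inclusion_prob >= 0 & f$inclusion_prob <= 1), info = m)
    } else {
      expect_true(all(f$inclusion_prob == 1), info = m)
    }
  }
})
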