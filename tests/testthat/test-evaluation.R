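test_that("fold plans partition samples evenly, balanced by class", {
  set.seed(1)
  y <- rbinom(622, 1, 0.4)
  f <- make_folds(y, k = 10, seed = 3)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(f) %in% c(62, 63)))
  # class balance: case counts per fold differ by at most one
  expect_lte(diff(range(table(f[y == 1]))), 1)
  # determinism / seed sensitivity
  expect_identical(make_folds(y, 10, seed = 3), f)
  expect_false(identical(make_folds(y, 10, seed = 4), f))
  expect_error(make_folds(rbinom(5, 1, 0.5), k = 10), "at least k")
})

test_that("AUC follows Mann-Whitney pair counting", {
  expect_equal(auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  # cases {0.9, 0.4} vs controls {0.7, 0.6, 0.2}: 4 of 6 pairs concordant
  expect_equal(auc(c(0.9, 0.4, 0.7, 0.6, 0.2), c(1, 1, 0, 0, 0)), 4 / 6)
  expect_error(auc(1:4, rep(1, 4)), "both classes")
  set.seed(2)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    s <- sample(round(runif(n), 2)) # rounded scores force ties
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(auc(s, l), oracle_auc_pairs(s, l), tolerance = 1e-12)
  }
})

test_that("the liability AUC ceiling behaves analytically", {
  expect_equal(max_liability_auc(0.0579, 0), 0.5)
  expect_equal(max_liability_auc(0.3, 0), 0.5)
  # strictly increasing in explained variance
  rho <- seq(0.05, 1, by = 0.05)
  vals <- sapply(rho, max_liability_auc, K = 0.0579)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals > 0.5 & vals < 1))
  expect_error(max_liability_auc(0, 0.4), "K must be")
  expect_error(max_liability_auc(0.1, 1.2), "rho2")
})

test_that("covariate-only logistic baseline calibrates to its generative AUC", {
  # null covariates: AUC ~ 0.5
  co0 <- simulate_cohort(sim_config(
    n_individuals = 600, n_snps = 20, n_causal = 0, h2_liability = 0,
    covariate_effects = c(weight = 0, sex = 0, neuter = 0),
    prevalence_K = 0.4, seed = 41
  ))
  b0 <- covariate_logistic_baseline(co0$samples, repeats = 1, seed = 2)
  expect_lt(abs(b0$mean_auc - 0.5), 0.07)
  # a single dominant Gaussian covariate with effect size d has binormal
  # AUC Phi(d / sqrt(2))
  set.seed(7)
  n <- 4000
  d <- 1.2
  y <- rep(c(1L, 0L), each = n / 2)
  samples <- data.frame(
    sample_id = sprintf("x%04d", 1:n), phenotype = y,
    sex = sample(c("female", "male"), n, TRUE),
    neutered = sample(c("intact", "neutered"), n, TRUE),
    weight = 30 + 4 * (rnorm(n) + d * y)
  )
  b1 <- covariate_logistic_baseline(samples, repeats = 1, seed = 3)
  expect_lt(abs(b1$mean_auc - pnorm(d / sqrt(2))), 0.03)
  # determinism
  b2 <- covariate_logistic_baseline(samples, repeats = 1, seed = 3)
  expect_equal(b1$mean_auc, b2$mean_auc)
})

test_that("cross-validation bookkeeping is leakage-safe and complete", {
  co <- small_signal_cohort(n = 200, p = 120, seed = 29)
  y <- co$samples$phenotype
  cv <- run_cv(co$genotypes, co$samples, classifier_spec("nb"),
               selection = list(method = "meandiff", k = 20),
               include_covariates = TRUE, k_folds = 5, repeats = 2, seed = 6)
  # every sample is scored exactly once per repeat
  expect_true(all(!is.na(cv$oof)))
  expect_equal(dim(cv$oof), c(200, 2))
  expect_equal(nrow(cv$fold_auc), 10)
  expect_true(all(cv$fold_auc$auc >= 0 & cv$fold_auc$auc <= 1))
  # folds partition the cohort within each repeat
  for (r in 1:2) expect_equal(sort(unique(cv$folds[, r])), 1:5)
  # summary statistics are consistent with the per-fold table
  expect_equal(cv$mean_auc, mean(cv$per_repeat$mean_fold_auc))
  expect_equal(cv$per_repeat$mean_fold_auc[1],
               mean(cv$fold_auc$auc[cv$fold_auc$rep == 1]))
  # signal + covariates beat the covariate-only baseline minus one SD
  base <- covariate_logistic_baseline(co$samples, k_folds = 5, repeats = 2, seed = 6)
  expect_gte(cv$mean_auc, base$mean_auc - base$sd_folds)
})

test_that("the Bayesian arm of the CV loop predicts above chance on signal", {
  co <- small_signal_cohort(n = 200, p = 100, seed = 37)
  cv <- run_cv(co$genotypes, co$samples,
               bayes_spec("BRR", n_iter = 500, burn_in = 100),
               include_covariates = TRUE, k_folds = 5, repeats = 1, seed = 9)
  expect_gt(cv$mean_auc, 0.6)
  expect_true(all(!is.na(cv$oof[, 1])))
})
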