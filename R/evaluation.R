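#' Assign samples to cross-validation folds
#'
#' Seeded random partition into `k` folds with sizes differing by at most
#' one. With `stratify = TRUE` (default) the case/control composition of
#' the folds is also balanced, which protects small cohorts from
#' single-class test partitions.
#'
#' @param y 0/1 labels (used for stratification; may contain the labels of
#'   all samples to be split).
#' @param k number of folds.
#' @param seed RNG seed; identical seeds give identical plans.
#' @param stratify balance classes across folds.
#' @return integer vector of fold ids in 1..k, aligned with `y`.
#' @export
make_folds <- function(y, k = 10, seed = 1, stratify = TRUE) {
  n <- length(y)
  if (n < k) stop("need at least k samples for k folds")
  set.seed(seed)
  fold <- integer(n)
  if (stratify) {
    ord <- c(sample(which(y == 1)), sample(which(y != 1)))
  } else {
    ord <- sample.int(n)
  }
  fold[ord] <- rep_len(sample.int(k), n)
  fold
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `(concordant pairs + 0.5 * tied pairs) / (n_case * n_control)`, computed
#' with midranks.
#'
#' @param scores numeric per-sample scores (higher = more case-like).
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1)
  n0 <- sum(labels != 1)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Maximum AUC attainable from a genomic profile under the liability
#' threshold model
#'
#' For a binary trait with population prevalence `K` and a predictor
#' explaining a proportion `rho2` of variance on the liability scale, the
#' ceiling on discrimination is
#' \deqn{AUC = \Phi\left(\frac{(i - v)\rho^2}
#'   {\sqrt{\rho^2[(1 - \rho^2 i(i - T)) + (1 - \rho^2 v(v - T))]}}\right)}
#' with threshold `T = qnorm(1 - K)`, height `z = dnorm(T)`, case mean
#' liability `i = z/K` and control mean liability `v = -z/(1 - K)`. With
#' `rho2` equal to the heritability this is the ceiling for a profile
#' capturing *all* genetic variance.
#'
#' @param K prevalence in (0, 1).
#' @param rho2 proportion of liability variance explained, in `[0, 1]`.
#' @return the AUC bound; 0.5 when `rho2 = 0`.
#' @export
max_liability_auc <- function(K, rho2) {
  if (K <= 0 || K >= 1) stop("K must be in (0, 1)")
  if (rho2 < 0 || rho2 > 1) stop("rho2 must be in [0, 1]")
  if (rho2 == 0) return(0.5)
  T <- stats::qnorm(1 - K)
  z <- stats::dnorm(T)
  i <- z / K
  v <- -z / (1 - K)
  num <- (i - v) * rho2
  den <- sqrt(rho2 * ((1 - rho2 * i * (i - T)) + (1 - rho2 * v * (v - T))))
  stats::pnorm(num / den)
}

#' Specification for a Bayesian probit model inside cross-validation
#'
#' @param model one of the five alphabet members (see [bayes_probit()]).
#' @param n_iter,burn_in,thin chain controls; defaults match
#'   [bayes_probit()] (52,000 / 6,000 / 5).
#' @param ... further arguments passed to [bayes_probit()] (`pi0`, `P0`,
#'   `df_prior`, `R2`).
#' @return list of class `bayes_probit_spec`.
#' @export
bayes_spec <- function(model = c("BRR", "BL", "BayesA", "BayesB", "BayesCpi"),
                       n_iter = 52000, burn_in = 6000, thin = 5, ...) {
  model <- match.arg(model)
  structure(list(model = model, n_iter = n_iter, burn_in = burn_in,
                 thin = thin, extra = list(...)),
            class = "bayes_probit_spec")
}

#' Repeated cross-validated genomic prediction
#'
#' The leakage-safe experimental loop: the data are split into `k_folds`
#' stratified folds that stay fixed across models within a repeat; inside
#' each fold, SNPs are ranked and selected using the *training* samples
#' only, the model is fitted on the training folds and scored on the
#' held-out fold; per-fold AUCs are averaged within a repeat and the whole
#' procedure is repeated with fresh fold seeds. Both the mean of per-fold
#' AUCs and the AUC of the aggregated out-of-fold predictions are recorded.
#'
#' @param genotypes post-QC dosage matrix.
#' @param samples sample table with `phenotype` and covariates.
#' @param model a [bayes_spec()], a [classifier_spec()], or
#'   `"covariates_only"` for the plain logistic baseline.
#' @param selection `NULL` to use all SNPs, or `list(method =, k =)` with
#'   method `"gwas"` or `"meandiff"` for within-fold top-k selection.
#' @param include_covariates add sex, neuter status and weight to the
#'   model (for classifiers this overrides the [classifier_spec()] flag).
#' @param k_folds,repeats folds per repeat and number of repeats.
#' @param seed base seed; repeat `r` uses fold seed `seed + r - 1`.
#' @param folds optional fixed fold assignment (single repeat) overriding
#'   fold construction.
#' @param stratify stratify folds by case status.
#' @return object of class `gprisk_cv`: `fold_auc` (per repeat x fold),
#'   `per_repeat` (mean fold AUC and aggregated AUC), `mean_auc`,
#'   `sd_repeats`, `sd_folds`, `oof` (out-of-fold score matrix, samples x
#'   repeats), and the call metadata.
#' @export
run_cv <- function(genotypes, samples, model, selection = NULL,
                   include_covariates = FALSE, k_folds = 10, repeats = 5,
                   seed = 1, folds = NULL, stratify = TRUE) {
  y <- samples$phenotype
  stopifnot(!anyNA(y), nrow(genotypes) == length(y))
  if (!is.null(selection)) {
    stopifnot(is.list(selection), selection$method %in% c("gwas", "meandiff"),
              selection$k >= 1)
  }
  n <- length(y)
  oof <- matrix(NA_real_, n, repeats)
  fold_rows <- list()
  rep_rows <- list()
  fold_store <- matrix(NA_integer_, n, repeats)

  for (r in seq_len(repeats)) {
    fold <- if (!is.null(folds)) folds else {
      make_folds(y, k = k_folds, seed = seed + r - 1, stratify = stratify)
    }
    fold_store[, r] <- fold
    for (f in sort(unique(fold))) {
      te <- fold == f
      tr <- !te
      if (length(unique(y[te])) < 2) {
        warning("repeat ", r, ", fold ", f, ": single-class test fold skipped")
        next
      }
      fit_seed <- seed * 1000 + r * 100 + f
      scores <- fit_and_score_fold(genotypes, samples, y, tr, te, model,
                                   selection, include_covariates, fit_seed)
      oof[te, r] <- scores
      fold_rows[[length(fold_rows) + 1]] <-
        data.frame(rep = r, fold = f, auc = auc(scores, y[te]),
                   n_test = sum(te), n_case_test = sum(y[te]))
    }
    rmask <- !is.na(oof[, r])
    this_rep <- do.call(rbind, fold_rows)
    this_rep <- this_rep[this_rep$rep == r, , drop = FALSE]
    rep_rows[[r]] <- data.frame(
      rep = r, mean_fold_auc = mean(this_rep$auc),
      aggregated_auc = auc(oof[rmask, r], y[rmask])
    )
  }

  fold_auc <- do.call(rbind, fold_rows)
  per_repeat <- do.call(rbind, rep_rows)
  structure(list(
    fold_auc = fold_auc,
    per_repeat = per_repeat,
    mean_auc = mean(per_repeat$mean_fold_auc),
    sd_repeats = stats::sd(per_repeat$mean_fold_auc),
    sd_folds = stats::sd(fold_auc$auc),
    aggregated_auc = mean(per_repeat$aggregated_auc),
    oof = oof, folds = fold_store,
    model = model, selection = selection,
    include_covariates = include_covariates,
    k_folds = k_folds, repeats = repeats, seed = seed
  ), class = "gprisk_cv")
}

#' @export
print.gprisk_cv <- function(x, ...) {
  lab <- if (inherits(x$model, "bayes_probit_spec")) x$model$model
  else if (inherits(x$model, "classifier_spec")) x$model$method
  else as.character(x$model)
  sel <- if (is.null(x$selection)) "all SNPs"
  else sprintf("%s top-%d", x$selection$method, x$selection$k)
  cat(sprintf("%d-fold CV x %d repeat(s): %s (%s%s)\n", x$k_folds, x$repeats,
              lab, sel, if (x$include_covariates) " + covariates" else ""))
  cat(sprintf("  mean AUC %.3f (SD %.3f across repeats, %.3f across folds)\n",
              x$mean_auc, x$sd_repeats, x$sd_folds))
  cat(sprintf("  aggregated out-of-fold AUC %.3f\n", x$aggregated_auc))
  invisible(x)
}

# one fold of the CV: select features on training samples, fit, score test
fit_and_score_fold <- function(genotypes, samples, y, tr, te, model,
                               selection, include_covariates, fit_seed) {
  covs_tr <- if (include_covariates) covariate_matrix(samples[tr, , drop = FALSE])
  covs_te <- if (include_covariates) covariate_matrix(samples[te, , drop = FALSE])

  g_tr <- genotypes[tr, , drop = FALSE]
  g_te <- genotypes[te, , drop = FALSE]
  if (!is.null(selection) && ncol(genotypes) > 0) {
    ranked <- rank_snps(g_tr, y[tr], covariates = covs_tr,
                        method = selection$method)
    keep <- select_top_k(ranked, selection$k)
    g_tr <- g_tr[, keep, drop = FALSE]
    g_te <- g_te[, keep, drop = FALSE]
  }

  if (identical(model, "covariates_only")) {
    df <- data.frame(y = y, covariate_matrix(samples))
    m <- stats::glm(y ~ ., data = df[tr, , drop = FALSE],
                    family = stats::binomial())
    return(as.numeric(stats::predict(m, newdata = df[te, , drop = FALSE],
                                     type = "response")))
  }
  if (inherits(model, "bayes_probit_spec")) {
    fit <- do.call(bayes_probit, c(
      list(genotypes = g_tr, y = y[tr], covariates = covs_tr,
           model = model$model, n_iter = model$n_iter,
           burn_in = model$burn_in, thin = model$thin, seed = fit_seed),
      model$extra
    ))
    return(predict(fit, genotypes = g_te, covariates = covs_te))
  }
  if (inherits(model, "classifier_spec")) {
    model$seed <- fit_seed
    x_tr <- build_features(g_tr, samples[tr, , drop = FALSE],
                           include_covariates = include_covariates)
    x_te <- build_features(g_te, samples[te, , drop = FALSE],
                           include_covariates = include_covariates,
                           stats = attr(x_tr, "stats"))
    fit <- fit_classifier(model, x_tr, y[tr])
    return(predict_classifier(fit, x_te))
  }
  stop("unknown model specification")
}

#' Cross-validated logistic baseline on the clinical covariates
#'
#' 10-fold CV of a plain logistic regression on sex, neuter status and
#' body weight -- the no-genetics reference every genomic model is compared
#' against.
#'
#' @inheritParams run_cv
#' @return a `gprisk_cv` object.
#' @export
covariate_logistic_baseline <- function(samples, k_folds = 10, repeats = 5,
                                        seed = 1, stratify = TRUE) {
  if (anyNA(samples$weight) || anyNA(samples$sex) || anyNA(samples$neutered)) {
    stop("covariates must be complete")
  }
  g0 <- matrix(integer(0), nrow = nrow(samples), ncol = 0)
  run_cv(g0, samples, model = "covariates_only", selection = NULL,
         include_covariates = TRUE, k_folds = k_folds, repeats = repeats,
         seed = seed, stratify = stratify)
}

#' Out-of-fold scores for the 8 base models
#'
#' Runs the four classifiers under both feature-selection filters on one
#' shared fold plan and returns the out-of-fold score matrix that the
#' ensemble layer consumes.
#'
#' @param genotypes post-QC dosage matrix.
#' @param samples sample table.
#' @param k SNP inclusion threshold for both filters.
#' @param include_covariates add covariates to every base model.
#' @param folds fold assignment shared by all base models (see
#'   [make_folds()]).
#' @param seed base seed for the learners.
#' @param nrounds,n_trees optional reduced sizes for the boosted trees /
#'   forest (defaults are the full 1000/1000).
#' @return samples x 8 score matrix with columns `<method>_<filter>`, plus
#'   attribute `"folds"`.
#' @export
base_predictions <- function(genotypes, samples, k, include_covariates = TRUE,
                             folds, seed = 1, nrounds = 1000, n_trees = 1000) {
  combos <- expand.grid(method = c("wrf", "gbt", "nb", "knn"),
                        filter = c("gwas", "meandiff"),
                        stringsAsFactors = FALSE)
  out <- sapply(seq_len(nrow(combos)), function(i) {
    spec <- classifier_spec(combos$method[i], seed = seed + i,
                            nrounds = nrounds, n_trees = n_trees)
    cv <- run_cv(genotypes, samples, spec,
                 selection = list(method = combos$filter[i], k = k),
                 include_covariates = include_covariates,
                 repeats = 1, seed = seed, folds = folds)
    cv$oof[, 1]
  })
  colnames(out) <- paste(combos$method, combos$filter, sep = "_")
  rownames(out) <- samples$sample_id
  attr(out, "folds") <- folds
  out
}
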