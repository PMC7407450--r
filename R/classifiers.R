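#' Classifier specification
#'
#' Bundles a classification method with its hyperparameters. Defaults are
#' the tuned values used throughout: weighted subspace random forest with
#' 1000 trees and `floor(sqrt(p))` candidate features; gradient boosted
#' trees with `eta = 0.05`, `gamma = 0.3`, depth 10, column and row
#' subsampling 0.8, 1000 rounds and the binary classification error rate as
#' training metric; naive Bayes with Laplace smoothing; k-nearest
#' neighbours with the five closest neighbours on standardized features.
#'
#' @param method `"wrf"`, `"gbt"`, `"nb"` or `"knn"`.
#' @param include_covariates add the clinical covariates (sex, neuter
#'   status, standardized weight) as extra feature columns.
#' @param seed RNG seed for the stochastic learners.
#' @param n_trees (wrf) number of trees, at least 1000 by default.
#' @param uniform_weights (wrf) if `TRUE`, candidate features are sampled
#'   uniformly, reducing wRF to an ordinary random forest.
#' @param eta,gamma,max_depth,colsample,subsample,nrounds (gbt) boosting
#'   hyperparameters.
#' @param laplace (nb) Laplace smoothing count for the categorical
#'   genotype likelihoods.
#' @param k_neighbors (knn) neighbourhood size.
#' @return list of class `classifier_spec`.
#' @export
classifier_spec <- function(method = c("wrf", "gbt", "nb", "knn"),
                            include_covariates = TRUE, seed = 1,
                            n_trees = 1000, uniform_weights = FALSE,
                            eta = 0.05, gamma = 0.3, max_depth = 10,
                            colsample = 0.8, subsample = 0.8, nrounds = 1000,
                            laplace = 1, k_neighbors = 5) {
  method <- match.arg(method)
  structure(list(method = method, include_covariates = include_covariates,
                 seed = seed, n_trees = n_trees,
                 uniform_weights = uniform_weights,
                 eta = eta, gamma = gamma, max_depth = max_depth,
                 colsample = colsample, subsample = subsample,
                 nrounds = nrounds, laplace = laplace,
                 k_neighbors = k_neighbors),
            class = "classifier_spec")
}

#' Assemble a numeric feature block from selected SNPs and covariates
#'
#' Missing dosages are mean-imputed and covariate weight standardized with
#' *training* statistics only; pass the `stats` attribute of the training
#' block when building the matching test block.
#'
#' @param genotypes dosage matrix restricted to the selected SNPs.
#' @param samples sample table (for the covariates).
#' @param include_covariates append sex (0/1), neuter status (0/1) and
#'   standardized weight columns.
#' @param stats training statistics from a previous call, or `NULL` to
#'   compute them from this (training) block.
#' @return numeric matrix; attribute `"stats"` holds the training
#'   imputation means and weight mean/sd.
#' @export
build_features <- function(genotypes, samples = NULL, include_covariates = FALSE,
                           stats = NULL) {
  x <- impute_mean(genotypes, means = stats$geno_means)
  geno_means <- attr(x, "imputation_means")
  attr(x, "imputation_means") <- NULL
  if (include_covariates) {
    if (is.null(samples)) stop("samples table required when covariates are included")
    wm <- if (is.null(stats)) mean(samples$weight) else stats$weight_mean
    ws <- if (is.null(stats)) stats::sd(samples$weight) else stats$weight_sd
    if (is.na(ws) || ws == 0) ws <- 1
    x <- cbind(x,
               cov_weight = (samples$weight - wm) / ws,
               cov_sex = as.numeric(samples$sex == "male"),
               cov_neutered = as.numeric(samples$neutered == "neutered"))
  } else {
    wm <- NA_real_; ws <- NA_real_
  }
  attr(x, "stats") <- list(geno_means = geno_means, weight_mean = wm,
                           weight_sd = ws)
  x
}

#' Class-association feature weights
#'
#' Weight of each feature is its absolute point-biserial correlation with
#' the case/control label, floored at `1e-6` (constant features get the
#' floor) and normalized to sum to one. Used as sampling probabilities for
#' the candidate-feature subspaces of the weighted random forest.
#'
#' @param features numeric feature matrix.
#' @param y binary 0/1 labels.
#' @return numeric vector of probabilities summing to 1.
#' @export
feature_weights <- function(features, y) {
  if (length(unique(y)) < 2) stop("both classes must be present")
  w <- abs(suppressWarnings(stats::cor(features, y)))[, 1]
  w[is.na(w)] <- 0
  w <- pmax(w, 1e-6)
  w / sum(w)
}

#' Fit a classification learner
#'
#' @param spec a [classifier_spec()].
#' @param features numeric training feature matrix from [build_features()].
#' @param y binary 0/1 training labels; both classes required.
#' @return fitted model object of class `gprisk_classifier`.
#' @details The weighted subspace random forest samples the candidate
#'   features considered at each split with probabilities proportional to
#'   [feature_weights()], so class-informative features enter the tree
#'   subspaces more often; with `uniform_weights = TRUE` it is an ordinary
#'   random forest. Naive Bayes treats dosage, sex and neuter columns as
#'   categorical and weight as Gaussian. KNN stores the training block with
#'   all columns standardized by training mean/sd.
#' @export
fit_classifier <- function(spec, features, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  if (nrow(features) < 10) stop("need at least 10 training samples")
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  p <- ncol(features)
  model <- switch(
    spec$method,
    wrf = {
      w <- if (spec$uniform_weights) rep(1 / p, p) else feature_weights(features, y)
      ranger::ranger(
        y = factor(y, levels = c(0, 1)), x = as.data.frame(features),
        num.trees = spec$n_trees, mtry = max(1L, floor(sqrt(p))),
        split.select.weights = as.numeric(w), probability = TRUE,
        seed = spec$seed, num.threads = 1
      )
    },
    gbt = {
      dtrain <- xgboost::xgb.DMatrix(features, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(eta = spec$eta, gamma = spec$gamma,
                      max_depth = spec$max_depth,
                      colsample_bytree = spec$colsample,
                      subsample = spec$subsample,
                      objective = "binary:logistic", eval_metric = "error",
                      nthread = 1, seed = spec$seed),
        data = dtrain, nrounds = spec$nrounds, verbose = 0
      )
    },
    nb = {
      df <- nb_frame(features)
      e1071::naiveBayes(x = df, y = factor(y, levels = c(0, 1)),
                        laplace = spec$laplace)
    },
    knn = {
      mu <- colMeans(features)
      sdv <- apply(features, 2, stats::sd)
      sdv[sdv == 0] <- 1
      list(train = scale(features, center = mu, scale = sdv),
           y = factor(y, levels = c(0, 1)), center = mu, scale = sdv)
    }
  )
  structure(list(model = model, spec = spec, layout = colnames(features)),
            class = "gprisk_classifier")
}

# dosage/sex/neuter columns as factors (dosages rounded to the nearest
# integer class after imputation), weight numeric
nb_frame <- function(features) {
  df <- as.data.frame(features)
  for (nm in names(df)) {
    if (nm == "cov_weight") next
    lev <- if (startsWith(nm, "cov_")) c(0, 1) else c(0, 1, 2)
    df[[nm]] <- factor(pmin(pmax(round(df[[nm]]), min(lev)), max(lev)),
                       levels = lev)
  }
  df
}

#' Predict case scores from a fitted classifier
#'
#' Returns a per-sample score in `[0, 1]`: mean tree probability (wrf),
#' boosted-tree probability (gbt), posterior class probability (nb), or the
#' fraction of the k nearest training neighbours that are cases (knn).
#'
#' @param fit a [fit_classifier()] result.
#' @param features feature matrix with the training layout.
#' @return numeric scores in `[0, 1]`.
#' @export
predict_classifier <- function(fit, features) {
  stopifnot(inherits(fit, "gprisk_classifier"))
  if (!identical(colnames(features), fit$layout)) {
    stop("feature layout mismatch with the fitted classifier")
  }
  spec <- fit$spec
  switch(
    spec$method,
    wrf = {
      pr <- stats::predict(fit$model, data = as.data.frame(features),
                           num.threads = 1)$predictions
      as.numeric(pr[, "1"])
    },
    gbt = {
      as.numeric(stats::predict(fit$model,
                                xgboost::xgb.DMatrix(features, nthread = 1)))
    },
    nb = {
      pr <- stats::predict(fit$model, newdata = nb_frame(features), type = "raw")
      as.numeric(pr[, "1"])
    },
    knn = {
      test <- scale(features, center = fit$model$center, scale = fit$model$scale)
      pred <- class::knn(train = fit$model$train, test = test,
                         cl = fit$model$y, k = spec$k_neighbors, prob = TRUE)
      pw <- attr(pred, "prob")
      ifelse(pred == "1", pw, 1 - pw)
    }
  )
}
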