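#' Bayesian whole-genome probit regression
#'
#' Fits a probit model for a binary phenotype, `P(y_i = 1) = Phi(eta_i)`
#' with linear predictor `eta_i = mu + x_i' b + sum_j m_ij alpha_j`, by
#' Gibbs sampling with the classical latent-variable augmentation: a latent
#' liability `l_i ~ N(eta_i, 1)` is truncated to the positive half-line for
#' cases and the non-positive half-line for controls. The residual variance
#' is fixed at 1 (it is not likelihood-identified) and the threshold at 0,
#' with a free intercept absorbing the location.
#'
#' The five members of the "Bayesian alphabet" differ only in the prior on
#' marker effects:
#' \describe{
#'   \item{BRR}{independent Gaussian prior with a common variance
#'     (homogeneous shrinkage).}
#'   \item{BL}{Bayesian LASSO: double-exponential (Laplace) prior via the
#'     exponential scale-mixture representation, with a Gamma hyperprior on
#'     the regularization parameter `lambda^2`.}
#'   \item{BayesA}{per-marker variances with scaled-inverse-chi-square
#'     updates, i.e. a scaled-t prior on effects.}
#'   \item{BayesB}{spike at zero plus a scaled-t slab; the per-marker
#'     inclusion indicator is sampled from its conditional odds and the
#'     mixture proportion `pi` (probability of *no* effect) carries a
#'     `Beta(P0*pi0, P0*(1-pi0))` prior.}
#'   \item{BayesCpi}{spike at zero plus a Gaussian slab with common
#'     variance; `pi` sampled as in BayesB.}
#' }
#'
#' Hyperpriors follow the usual weakly-informative default rules:
#' scaled-t components use `df_prior` degrees of freedom with the scale
#' solved from the `R2` heuristic against the variance carried by the
#' (centred) markers; the default chain length is 52,000 iterations with a
#' 6,000-iteration burn-in.
#'
#' @param genotypes dosage matrix (0/1/2/`NA`), samples x SNPs. Missing
#'   entries are mean-imputed and columns are centred; training column
#'   means are stored and re-applied by [predict.bayes_probit()].
#' @param y binary 0/1 phenotype; both classes must be present.
#' @param covariates optional numeric matrix of fixed-effect columns (see
#'   [covariate_matrix()]); assigned flat priors.
#' @param model one of `"BRR"`, `"BL"`, `"BayesA"`, `"BayesB"`, `"BayesCpi"`.
#' @param n_iter,burn_in,thin chain length, burn-in, thinning interval.
#' @param pi0,P0 prior mean and concentration of the Beta prior on the
#'   mixture proportion `pi` (BayesB/Cpi).
#' @param df_prior degrees of freedom of scaled-inverse-chi-square priors.
#' @param R2 heuristic fraction of latent variance attributed a priori to
#'   the markers; sets prior scales.
#' @param seed RNG seed; identical seeds give identical chains.
#' @param fixed_marker_var if non-`NULL`, the marker-effect (slab) variance
#'   is held at this value instead of being sampled (validation aid: makes
#'   the prior on effects exactly `N(0, fixed_marker_var)` for BRR).
#' @return An object of class `bayes_probit` with posterior summaries:
#'   `coefficients` (posterior means: `intercept`, `covariates`,
#'   `markers`), posterior SDs, `inclusion_prob` (per-SNP mean of the
#'   indicator), `pi_mean`, plug-in `fitted` probabilities,
#'   posterior-averaged `fitted_bayes` probabilities, and a `trace` matrix
#'   of scalar parameters.
#' @references The probit augmentation is the Albert-Chib scheme; the
#'   marker priors are the standard genomic-prediction "alphabet".
#' @export
bayes_probit <- function(genotypes, y, covariates = NULL,
                         model = c("BRR", "BL", "BayesA", "BayesB", "BayesCpi"),
                         n_iter = 52000, burn_in = 6000, thin = 5,
                         pi0 = 0.5, P0 = 10, df_prior = 5, R2 = 0.5,
                         seed = 1, fixed_marker_var = NULL) {
  model <- match.arg(model)
  y <- as.integer(y)
  if (anyNA(y) || !all(y %in% c(0L, 1L))) stop("y must be binary 0/1 without NA")
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  stopifnot(burn_in < n_iter, thin >= 1, pi0 > 0, pi0 < 1, P0 > 0)

  if (is.null(genotypes)) {
    genotypes <- matrix(numeric(0), nrow = length(y), ncol = 0)
  }
  stopifnot(nrow(genotypes) == length(y))
  p <- ncol(genotypes)
  M <- impute_mean(genotypes)
  centers <- colMeans(M)
  M <- sweep(M, 2, centers)

  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == length(y))
    storage.mode(covariates) <- "double"
    if (anyNA(covariates)) stop("covariates must be complete")
  } else {
    covariates <- matrix(numeric(0), nrow = length(y), ncol = 0)
  }

  # prior scales from the R2 rule: markers jointly carry about R2 of the
  # latent variance, residual variance being fixed at 1
  msx <- if (p > 0) sum(apply(M, 2, stats::var)) else 0
  vg_target <- R2 / (1 - R2)
  frac_in <- if (model %in% c("BayesB", "BayesCpi")) (1 - pi0) else 1
  m0 <- if (msx > 0) vg_target / (msx * frac_in) else 0.01
  S0 <- m0 * (df_prior + 2) / df_prior
  lambda2_hat <- if (msx > 0) 2 * msx * (1 - R2) / R2 else 1
  l_shape <- 1.1
  l_rate <- (l_shape - 1) / lambda2_hat

  model_code <- match(model, c("BRR", "BL", "BayesA", "BayesB", "BayesCpi"))
  set.seed(seed)
  fit <- .gibbs_probit(M, covariates, y, model_code,
                       as.integer(n_iter), as.integer(burn_in), as.integer(thin),
                       df_prior, S0, pi0, P0, l_shape, l_rate, lambda2_hat,
                       if (is.null(fixed_marker_var)) -1 else fixed_marker_var)

  eta <- fit$mu_mean +
    (if (ncol(covariates) > 0) as.numeric(covariates %*% fit$b_mean) else 0) +
    (if (p > 0) as.numeric(M %*% fit$alpha_mean) else 0)

  b_mean <- as.numeric(fit$b_mean)
  names(b_mean) <- colnames(covariates)
  alpha_mean <- as.numeric(fit$alpha_mean)
  names(alpha_mean) <- colnames(genotypes)
  colnames(fit$trace) <- c("mu", "pi", "marker_var", "lambda2")

  structure(list(
    model = model,
    coefficients = list(intercept = fit$mu_mean, covariates = b_mean,
                        markers = alpha_mean),
    posterior_sd = list(intercept = fit$mu_sd,
                        covariates = as.numeric(fit$b_sd),
                        markers = as.numeric(fit$alpha_sd)),
    inclusion_prob = as.numeric(fit$delta_mean),
    pi_mean = fit$pi_mean,
    fitted = stats::pnorm(eta),
    fitted_bayes = as.numeric(fit$prob_mean),
    linear_predictor = eta,
    centers = centers,
    snp_ids = colnames(genotypes),
    cov_names = colnames(covariates),
    y = y,
    spec = list(n_iter = n_iter, burn_in = burn_in, thin = thin, pi0 = pi0,
                P0 = P0, df_prior = df_prior, R2 = R2, seed = seed,
                n_samples = fit$n_samples),
    trace = fit$trace
  ), class = "bayes_probit")
}

#' @export
print.bayes_probit <- function(x, ...) {
  cat("Bayesian probit whole-genome regression (", x$model, ")\n", sep = "")
  cat(sprintf("  %d samples (%d cases), %d markers, %d covariates\n",
              length(x$y), sum(x$y), length(x$coefficients$markers),
              length(x$coefficients$covariates)))
  cat(sprintf("  chain: %d iterations, %d burn-in, thin %d (%d samples kept)\n",
              x$spec$n_iter, x$spec$burn_in, x$spec$thin, x$spec$n_samples))
  if (length(x$coefficients$covariates) == 0) {
    cat(sprintf("  posterior mean intercept %.3f => baseline Phi(mu) = %.3f\n",
                x$coefficients$intercept, stats::pnorm(x$coefficients$intercept)))
  } else {
    cat(sprintf("  posterior mean intercept %.3f; mean fitted probability %.3f\n",
                x$coefficients$intercept, mean(x$fitted)))
  }
  if (x$model %in% c("BayesB", "BayesCpi")) {
    cat(sprintf("  posterior mean pi (null-marker proportion) = %.3f\n", x$pi_mean))
  }
  invisible(x)
}

#' @export
summary.bayes_probit <- function(object, ...) {
  co <- object$coefficients
  out <- list(
    model = object$model,
    n = length(object$y), n_case = sum(object$y),
    p = length(co$markers),
    intercept = c(mean = co$intercept, sd = object$posterior_sd$intercept),
    covariates = if (length(co$covariates))
      data.frame(mean = co$covariates, sd = object$posterior_sd$covariates)
      else NULL,
    pi_mean = object$pi_mean,
    marker_effect_range = if (length(co$markers)) range(co$markers) else NULL,
    mean_inclusion = mean(object$inclusion_prob)
  )
  class(out) <- "summary.bayes_probit"
  out
}

#' @export
print.summary.bayes_probit <- function(x, ...) {
  cat(sprintf("%s: n = %d (%d cases), p = %d markers\n",
              x$model, x$n, x$n_case, x$p))
  cat(sprintf("  intercept %.3f (sd %.3f)\n", x$intercept["mean"], x$intercept["sd"]))
  if (!is.null(x$covariates)) {
    cat("  covariate effects:\n")
    print(round(x$covariates, 4))
  }
  if (x$p > 0) {
    cat(sprintf("  marker effects in [%.4g, %.4g]; mean inclusion prob %.3f\n",
                x$marker_effect_range[1], x$marker_effect_range[2],
                x$mean_inclusion))
  }
  invisible(x)
}

#' @export
coef.bayes_probit <- function(object, ...) {
  co <- object$coefficients
  c("(Intercept)" = co$intercept, co$covariates, co$markers)
}

#' @export
fitted.bayes_probit <- function(object, ...) object$fitted

#' Predict case probabilities from a fitted Bayesian probit model
#'
#' Plug-in prediction `Phi(mu + X b + M alpha)` at the posterior means,
#' with new dosages imputed and centred using the *training* column means.
#'
#' @param object a [bayes_probit()] fit.
#' @param genotypes dosage matrix whose columns match the training SNP set.
#' @param covariates covariate matrix with the training layout (or `NULL`
#'   if the model had none).
#' @param type `"response"` for probabilities, `"link"` for the linear
#'   predictor.
#' @param ... unused.
#' @return numeric vector of per-sample values.
#' @export
predict.bayes_probit <- function(object, genotypes = NULL, covariates = NULL,
                                 type = c("response", "link"), ...) {
  type <- match.arg(type)
  p <- length(object$snp_ids)
  if (p > 0) {
    if (is.null(genotypes) || ncol(genotypes) != p ||
        !identical(colnames(genotypes), object$snp_ids)) {
      stop("SNP mismatch: prediction genotypes must have the training SNP columns")
    }
    M <- impute_mean(genotypes, means = object$centers)
    M <- sweep(M, 2, object$centers)
    gterm <- as.numeric(M %*% object$coefficients$markers)
  } else gterm <- 0
  q <- length(object$cov_names)
  if (q > 0) {
    covariates <- as.matrix(covariates)
    if (is.null(covariates) || ncol(covariates) != q) {
      stop("covariate layout mismatch with the fitted model")
    }
    cterm <- as.numeric(covariates %*% object$coefficients$covariates)
  } else cterm <- 0
  eta <- object$coefficients$intercept + cterm + gterm
  if (type == "link") eta else stats::pnorm(eta)
}

#' Numeric covariate matrix for the clinical risk factors
#'
#' Encodes the three covariates as model columns: `weight` in kg (numeric),
#' `sex` as male = 1 / female = 0, `neutered` as neutered = 1 / intact = 0.
#'
#' @param samples sample table with `sex`, `neutered`, `weight`.
#' @return numeric matrix with columns `weight`, `sex_male`, `neutered`.
#' @export
covariate_matrix <- function(samples) {
  out <- cbind(
    weight = samples$weight,
    sex_male = as.numeric(samples$sex == "male"),
    neutered = as.numeric(samples$neutered == "neutered")
  )
  rownames(out) <- samples$sample_id
  out
}
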