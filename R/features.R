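#' Genomic relationship matrix (VanRaden)
#'
#' `K = W W' / sum_j 2 p_j (1 - p_j)` where `W` is the mean-imputed dosage
#' matrix with column means `2 p_j` subtracted.
#'
#' @param genotypes dosage matrix (0/1/2/`NA`).
#' @return n x n symmetric relationship matrix.
#' @export
grm <- function(genotypes) {
  if (nrow(genotypes) < 2) stop("need at least 2 samples")
  x <- impute_mean(genotypes)
  pj <- colMeans(x) / 2
  denom <- sum(2 * pj * (1 - pj))
  vars <- colMeans(x^2) - colMeans(x)^2
  if (denom <= 0 || all(vars < 1e-12)) {
    stop("all SNPs are monomorphic; relationship matrix undefined")
  }
  w <- sweep(x, 2, 2 * pj)
  tcrossprod(w) / denom
}

#' Linear mixed model association scan
#'
#' Single-marker association of a 0/1 phenotype (treated as quantitative;
#' the scan is a ranking device) with a polygenic random effect whose
#' covariance is `sigma2_g * K`. The two variance components are estimated
#' once by REML on the null (covariates-only) model via the
#' eigendecomposition of `K`; each SNP is then tested by a Wald t-test in
#' the rotated, whitened regression with the variance *ratio* held fixed
#' (EMMAX-style). With `K = I` this reduces exactly to the ordinary
#' least-squares t-test.
#'
#' @param genotypes dosage matrix (training samples only).
#' @param y binary 0/1 response.
#' @param covariates optional numeric matrix of fixed-effect columns.
#' @param K kinship matrix from [grm()] (or identity).
#' @return data.frame with `snp_id`, `beta`, `se`, `p`.
#' @export
lmm_gwas <- function(genotypes, y, covariates = NULL, K) {
  n <- nrow(genotypes)
  stopifnot(length(y) == n, nrow(K) == n, ncol(K) == n)
  eg <- eigen(K + diag(1e-8, n), symmetric = TRUE)
  if (min(eg$values) < -1e-6) stop("kinship matrix is not positive semi-definite")
  d <- pmax(eg$values, 1e-10)
  U <- eg$vectors

  X0 <- cbind(intercept = rep(1, n), covariates)
  qr0 <- qr(X0)
  if (qr0$rank < ncol(X0)) {
    warning("dropping ", ncol(X0) - qr0$rank, " collinear covariate column(s)")
    X0 <- X0[, qr0$pivot[seq_len(qr0$rank)], drop = FALSE]
  }
  q <- ncol(X0)
  yt <- crossprod(U, y)
  X0t <- crossprod(U, X0)

  # REML profile over log(delta), delta = sigma2_e / sigma2_g
  reml_neg <- function(logdelta) {
    delta <- exp(logdelta)
    wts <- 1 / (d + delta)
    Xw <- X0t * sqrt(wts)
    yw <- yt * sqrt(wts)
    fit <- stats::lm.fit(Xw, yw)
    rss <- sum(fit$residuals^2)
    s2g <- rss / (n - q)
    0.5 * ((n - q) * log(s2g) + sum(log(d + delta)) +
             determinant(crossprod(Xw), logarithm = TRUE)$modulus[1] + (n - q))
  }
  opt <- stats::optimize(reml_neg, c(-12, 12))
  delta <- exp(opt$minimum)

  s <- 1 / sqrt(d + delta)
  yw <- as.numeric(yt) * s
  Xw <- X0t * s
  Mw <- crossprod(U, impute_mean(genotypes)) * s

  qrw <- qr(Xw)
  yr <- qr.resid(qrw, yw)
  Mr <- qr.resid(qrw, Mw)
  css <- colSums(Mr^2)
  sy <- as.numeric(crossprod(Mr, yr))
  beta <- ifelse(css > 1e-12, sy / css, 0)
  rss <- pmax(sum(yr^2) - beta^2 * css, 0)
  df <- n - q - 1
  sigma2 <- rss / df
  se <- ifelse(css > 1e-12, sqrt(sigma2 / css), NA_real_)
  tstat <- ifelse(is.na(se) | se == 0, 0, beta / se)
  pval <- 2 * stats::pt(-abs(tstat), df)
  pval[css <= 1e-12] <- 1

  data.frame(snp_id = colnames(genotypes), beta = beta, se = se, p = pval,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank SNPs within a training set
#'
#' The two univariate filters used ahead of the classifiers:
#' `"gwas"` ranks by ascending mixed-model association p-value
#' ([lmm_gwas()], kinship built from the same training genotypes);
#' `"meandiff"` ranks by descending absolute difference in allele frequency
#' between cases and controls, `|freq_cases - freq_controls|` with
#' `freq = sum(dosages) / (2 * n_nonmissing)`. Ties are broken by
#' lexicographic SNP id for cross-platform determinism.
#'
#' @param genotypes training dosage matrix.
#' @param y training 0/1 phenotype.
#' @param covariates optional covariate matrix (used by the GWAS filter).
#' @param method `"gwas"` or `"meandiff"`.
#' @return data.frame of class `ranked_features`: `snp_id`, `score`
#'   (p-value or `|dfreq|`), `rank`; attribute `method`.
#' @export
rank_snps <- function(genotypes, y, covariates = NULL,
                      method = c("gwas", "meandiff")) {
  method <- match.arg(method)
  if (length(unique(y[!is.na(y)])) < 2) stop("both classes must be present")
  if (method == "meandiff") {
    fcase <- class_allele_freq(genotypes, y == 1)
    fctrl <- class_allele_freq(genotypes, y == 0)
    score <- abs(fcase - fctrl)
    score[is.na(score)] <- 0
    ord <- order(-score, colnames(genotypes))
  } else {
    K <- grm(genotypes)
    gw <- lmm_gwas(genotypes, y, covariates, K)
    score <- gw$p
    ord <- order(score, colnames(genotypes))
  }
  out <- data.frame(snp_id = colnames(genotypes)[ord], score = score[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  attr(out, "method") <- method
  class(out) <- c("ranked_features", "data.frame")
  out
}

class_allele_freq <- function(genotypes, mask) {
  g <- genotypes[mask, , drop = FALSE]
  colSums(g, na.rm = TRUE) / (2 * colSums(!is.na(g)))
}

#' Take the top k ranked SNPs
#'
#' @param ranked a [rank_snps()] result.
#' @param k number of SNPs; if larger than available, all are returned.
#' @return character vector of SNP ids, best first.
#' @export
select_top_k <- function(ranked, k) {
  stopifnot(inherits(ranked, "ranked_features"), k >= 1)
  ranked$snp_id[seq_len(min(k, nrow(ranked)))]
}
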