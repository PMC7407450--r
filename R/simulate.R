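#' Configuration for a simulated liability-threshold cohort
#'
#' Defaults emulate a Labrador Retriever case/control genotyping study:
#' roughly 622 dogs, a dense biallelic SNP panel organised in short
#' haplotype blocks (the breed's average block is about 20 kb; with one SNP
#' per kilobase that is 20 SNPs per block), a polygenic liability with
#' heritability 0.4 (published estimates run 0.3-0.5), a population
#' prevalence of 0.0579, and three clinical covariates (body weight, sex,
#' neuter status) with nonzero liability effects.
#'
#' @param n_individuals number of diploid individuals.
#' @param n_snps number of biallelic SNPs.
#' @param block_size SNPs per haplotype (LD) block.
#' @param within_block_r target correlation of adjacent within-block
#'   dosages, in (0, 1).
#' @param n_causal number of causal SNPs, drawn uniformly.
#' @param h2_liability heritability on the liability scale, in `[0, 1]`.
#' @param prevalence_K case prevalence, in (0, 1).
#' @param covariate_effects named numeric vector `c(weight =, sex =,
#'   neuter =)` of liability-scale effects; weight is per kg (centred),
#'   sex is the male-vs-female contrast, neuter the neutered-vs-intact
#'   contrast.
#' @param maf_range range of block allele frequencies, within (0, 0.5].
#' @param missing_rate probability that a released genotype call is missing.
#' @param seed integer RNG seed; identical seeds give identical cohorts.
#' @param n_founders founder haplotypes per block.
#' @param mutation_rate per-allele probability that a copied founder allele
#'   is replaced by a fresh draw at the block frequency.
#' @param weight_mean named vector `c(female =, male =)` of mean body
#'   weight in kg.
#' @param weight_sd body-weight SD in kg.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 622,
                       n_snps = 100000,
                       block_size = 20,
                       within_block_r = 0.7,
                       n_causal = 1000,
                       h2_liability = 0.4,
                       prevalence_K = 0.0579,
                       covariate_effects = c(weight = 0.08, sex = 0.25, neuter = 0.45),
                       maf_range = c(0.1, 0.5),
                       missing_rate = 0.002,
                       seed = 1,
                       n_founders = 20,
                       mutation_rate = 0.02,
                       weight_mean = c(female = 30, male = 34),
                       weight_sd = 4) {
  cfg <- list(n_individuals = n_individuals, n_snps = n_snps,
              block_size = block_size, within_block_r = within_block_r,
              n_causal = n_causal, h2_liability = h2_liability,
              prevalence_K = prevalence_K, covariate_effects = covariate_effects,
              maf_range = maf_range, missing_rate = missing_rate, seed = seed,
              n_founders = n_founders, mutation_rate = mutation_rate,
              weight_mean = weight_mean, weight_sd = weight_sd)
  stopifnot(n_individuals >= 2, n_snps >= 1, block_size >= 1,
            within_block_r > 0, within_block_r < 1,
            n_causal >= 0, n_causal <= n_snps,
            h2_liability >= 0, h2_liability <= 1,
            prevalence_K > 0, prevalence_K < 1,
            length(covariate_effects) == 3,
            maf_range[1] > 0, maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
            missing_rate >= 0, missing_rate < 1,
            n_founders >= 2, mutation_rate >= 0, mutation_rate < 1)
  structure(cfg, class = "sim_config")
}

#' Simulate a case/control cohort under the liability threshold model
#'
#' Genotypes are built from per-block founder haplotype pools: within each
#' block a set of founder haplotypes carries alleles generated by a Markov
#' copying process along the block, individuals draw two haplotypes per
#' block from the pool, and each copied allele mutates (is redrawn at the
#' block allele frequency) with a small probability. The copy-persistence
#' probability is set to `within_block_r / (1 - mutation_rate)^2` so the
#' adjacent-SNP dosage correlation inside blocks approximates
#' `within_block_r`, while cross-block correlation is ~0.
#'
#' Liability is `genetic_score + covariate score + Normal noise`, where the
#' genetic score `sum_j m_ij alpha_j` is rescaled to have sample variance
#' exactly `h2_liability`, the covariate score is centred, and the noise
#' variance completes a total liability variance of 1. Cases are the
#' individuals whose liability exceeds the realized `1 - K` quantile, so
#' finite-sample prevalence matches `prevalence_K`. Missing genotype calls
#' are masked only *after* the genetic score is formed.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `sim_cohort` with components `genotypes`, `snps`,
#'   `samples` (as in [read_plink()], phenotype filled in), plus the
#'   generative truth: `true_effects` (per-SNP liability effects, 0 for
#'   non-causal), `genetic_score`, `true_liability`, `liability_threshold`,
#'   and `config`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_individuals
  p <- cfg$n_snps
  bs <- cfg$block_size
  n_blocks <- ceiling(p / bs)
  copy_prob <- cfg$within_block_r / (1 - cfg$mutation_rate)^2
  if (copy_prob >= 1) {
    stop("configuration error: within_block_r unreachable at this mutation_rate")
  }

  dos <- matrix(0L, nrow = n, ncol = p)
  block_freq <- stats::runif(n_blocks, cfg$maf_range[1], cfg$maf_range[2])
  for (b in seq_len(n_blocks)) {
    cols <- ((b - 1L) * bs + 1L):min(b * bs, p)
    m <- length(cols)
    fq <- block_freq[b]
    # founder haplotypes: first-order Markov copying along the block
    H <- matrix(0L, nrow = cfg$n_founders, ncol = m)
    H[, 1] <- stats::rbinom(cfg$n_founders, 1L, fq)
    if (m > 1) {
      for (k in 2:m) {
        keep <- stats::runif(cfg$n_founders) < copy_prob
        H[, k] <- ifelse(keep, H[, k - 1], stats::rbinom(cfg$n_founders, 1L, fq))
      }
    }
    h1 <- H[sample.int(cfg$n_founders, n, replace = TRUE), , drop = FALSE]
    h2 <- H[sample.int(cfg$n_founders, n, replace = TRUE), , drop = FALSE]
    if (cfg$mutation_rate > 0) {
      mut1 <- matrix(stats::runif(n * m) < cfg$mutation_rate, n, m)
      h1[mut1] <- stats::rbinom(sum(mut1), 1L, fq)
      mut2 <- matrix(stats::runif(n * m) < cfg$mutation_rate, n, m)
      h2[mut2] <- stats::rbinom(sum(mut2), 1L, fq)
    }
    dos[, cols] <- h1 + h2
  }

  snp_ids <- sprintf("snp%06d", seq_len(p))
  sample_ids <- sprintf("S%05d", seq_len(n))
  dimnames(dos) <- list(sample_ids, snp_ids)

  # polygenic liability
  true_effects <- numeric(p)
  genetic_score <- numeric(n)
  if (cfg$h2_liability > 0 && cfg$n_causal > 0) {
    causal <- sample.int(p, cfg$n_causal)
    alpha <- stats::rnorm(cfg$n_causal)
    g_raw <- as.numeric(dos[, causal, drop = FALSE] %*% alpha)
    sd_raw <- stats::sd(g_raw)
    if (sd_raw == 0) stop("configuration error: causal SNPs carry no variance")
    scale <- sqrt(cfg$h2_liability) / sd_raw
    true_effects[causal] <- alpha * scale
    genetic_score <- (g_raw - mean(g_raw)) * scale
  }

  # covariates
  eff <- cfg$covariate_effects
  sex_male <- stats::rbinom(n, 1L, 0.5)
  neutered <- stats::rbinom(n, 1L, 0.7)
  wmean <- ifelse(sex_male == 1L, cfg$weight_mean[["male"]], cfg$weight_mean[["female"]])
  weight <- stats::rnorm(n, wmean, cfg$weight_sd)
  weight <- pmax(weight, 5) # floor far in the tail; weights must stay positive
  cov_score <- eff[["weight"]] * (weight - mean(weight)) +
    eff[["sex"]] * sex_male + eff[["neuter"]] * neutered
  cov_score <- cov_score - mean(cov_score)

  res_var <- 1 - cfg$h2_liability - stats::var(cov_score)
  if (res_var < 0) {
    stop("configuration error: h2 + covariate variance exceed total liability variance 1")
  }
  liability <- genetic_score + cov_score + stats::rnorm(n, 0, sqrt(res_var))

  threshold <- stats::quantile(liability, 1 - cfg$prevalence_K, names = FALSE)
  phenotype <- as.integer(liability > threshold)

  if (cfg$missing_rate > 0) {
    miss <- which(stats::runif(n * p) < cfg$missing_rate)
    dos[miss] <- NA_integer_
  }

  snps <- data.frame(
    snp_id = snp_ids,
    chrom = "1",
    pos = seq_len(p) * 1000L,
    allele1 = "A", allele2 = "B",
    stringsAsFactors = FALSE
  )
  f <- colMeans(dos, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  snps$maf <- pmin(f, 1 - f)

  samples <- data.frame(
    sample_id = sample_ids,
    phenotype = phenotype,
    sex = ifelse(sex_male == 1L, "male", "female"),
    neutered = ifelse(neutered == 1L, "neutered", "intact"),
    weight = weight,
    stringsAsFactors = FALSE
  )

  structure(list(genotypes = dos, snps = snps, samples = samples,
                 true_effects = true_effects, genetic_score = genetic_score,
                 true_liability = liability, liability_threshold = threshold,
                 config = cfg),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cfg <- x$config
  cat("Simulated liability-threshold cohort\n")
  cat(sprintf("  %d individuals x %d SNPs (%d cases, prevalence target %.4f)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              sum(x$samples$phenotype), cfg$prevalence_K))
  cat(sprintf("  h2 = %.2f (realized %.3f), %d causal SNPs, block size %d\n",
              cfg$h2_liability, realized_heritability(x),
              sum(x$true_effects != 0), cfg$block_size))
  invisible(x)
}

#' Realized liability-scale heritability of a simulated cohort
#'
#' @param cohort a [simulate_cohort()] result.
#' @return `var(genetic_score) / var(true_liability)`.
#' @export
realized_heritability <- function(cohort) {
  stopifnot(inherits(cohort, "sim_cohort"))
  vl <- stats::var(cohort$true_liability)
  if (vl == 0) stop("zero-variance liability")
  stats::var(cohort$genetic_score) / vl
}

#' AUC of an arbitrary per-sample score against simulated case status
#'
#' Thin wrapper over [auc()] for generative-truth checks, e.g. the AUC of
#' the true genetic score, whose large-sample value is given by
#' [max_liability_auc()] at the cohort's heritability and prevalence.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param score numeric per-sample score aligned with the cohort's samples.
#' @return Mann-Whitney AUC.
#' @export
oracle_auc <- function(cohort, score) {
  stopifnot(inherits(cohort, "sim_cohort"))
  auc(score, cohort$samples$phenotype)
}
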