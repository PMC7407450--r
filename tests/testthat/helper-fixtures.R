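# shared fixture builders (all generated in code; no files on disk)

# random valid cohort pieces for round-trip tests
random_cohort <- function(n, p, missing_rate = 0.05, seed = 1) {
  set.seed(seed)
  freq <- runif(p, 0.05, 0.5)
  dos <- sapply(freq, function(f) rbinom(n, 2, f))
  if (missing_rate > 0) dos[runif(n * p) < missing_rate] <- NA_integer_
  storage.mode(dos) <- "integer"
  # orient to minor allele so write/read round-trips exactly
  fr <- colMeans(dos, na.rm = TRUE) / 2
  flip <- !is.nan(fr) & fr > 0.5
  dos[, flip] <- 2L - dos[, flip]
  snp_ids <- sprintf("rs%04d", seq_len(p))
  sample_ids <- sprintf("id%03d", seq_len(n))
  dimnames(dos) <- list(sample_ids, snp_ids)
  list(
    genotypes = dos,
    snps = data.frame(snp_id = snp_ids, chrom = "1",
                      pos = seq_len(p) * 100L,
                      allele1 = "A", allele2 = "G",
                      stringsAsFactors = FALSE),
    samples = data.frame(sample_id = sample_ids,
                         phenotype = rbinom(n, 1, 0.4),
                         sex = sample(c("female", "male"), n, replace = TRUE),
                         neutered = NA_character_, weight = NA_real_,
                         stringsAsFactors = FALSE)
  )
}

# a small balanced cohort with signal, reused by classifier/CV tests
small_signal_cohort <- function(n = 250, p = 300, seed = 7) {
  simulate_cohort(sim_config(
    n_individuals = n, n_snps = p, n_causal = 40,
    prevalence_K = 0.4, seed = seed
  ))
}
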