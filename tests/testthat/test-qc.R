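test_that("MAF computation folds and handles missingness", {
  g <- cbind(a = c(0L, 0L, 0L, 0L),
             b = c(2L, 2L, 2L, 2L),
             c = c(0L, 1L, 1L, 2L),
             d = c(0L, NA, 1L, NA))
  maf <- snp_maf(g)
  expect_equal(unname(maf), c(0, 0, 0.5, 0.25))
  expect_true(is.na(snp_maf(matrix(NA_integer_, 4, 1))[1]))
})

test_that("HWE exact p-values match hand cases and the enumeration oracle", {
  expect_equal(hwe_exact_p(0, 0, 100), 1)
  expect_equal(hwe_exact_p(25, 50, 25), oracle_hwe_p(25, 50, 25), tolerance = 1e-12)
  # all homozygotes, no hets: grossly out of equilibrium
  expect_lt(hwe_exact_p(50, 0, 50), 1e-7)
  expect_equal(hwe_exact_p(50, 0, 50), oracle_hwe_p(50, 0, 50), tolerance = 1e-12)
  # spot-check a grid against the recurrence oracle
  for (nAA in c(0, 3, 10)) for (nAa in c(0, 5, 20)) for (naa in c(1, 7)) {
    expect_equal(hwe_exact_p(nAA, nAa, naa), oracle_hwe_p(nAA, nAa, naa),
                 tolerance = 1e-12)
  }
  expect_error(hwe_exact_p(-1, 0, 2), "non-negative")
})

test_that("QC filters remove in fixed order with a faithful report", {
  set.seed(11)
  n <- 60
  good <- function() rbinom(n, 2, 0.3)
  g <- cbind(
    ok1 = good(), ok2 = good(), ok3 = good(),
    lowcall = replace(good(), 1:6, NA),          # call rate 0.9 <= 0.95
    rare = c(rep(0L, n - 3), 1L, 1L, 1L),        # MAF 0.025 <= 0.05
    hwe_bad = rep(c(0L, 2L), n / 2)              # no hets at MAF 0.5
  )
  storage.mode(g) <- "integer"
  snps <- data.frame(snp_id = colnames(g), chrom = "1", pos = 1:6 * 10L,
                     allele1 = "A", allele2 = "G", stringsAsFactors = FALSE)
  res <- apply_qc(g, snps)
  expect_equal(res$report$n_removed_callrate, 1)
  expect_equal(res$report$n_removed_maf, 1)
  expect_equal(res$report$n_removed_hwe, 1)
  expect_equal(res$report$n_remaining, 3)
  expect_setequal(res$snps$snp_id, c("ok1", "ok2", "ok3"))
  # removed + remaining account for every input SNP exactly once
  expect_equal(res$report$n_removed_callrate + res$report$n_removed_maf +
                 res$report$n_removed_hwe + res$report$n_remaining,
               res$report$n_input)
  # MAF exactly at the threshold is excluded (inclusive rule)
  m <- 40
  g2 <- cbind(edge = c(rep(1L, 4), rep(0L, m - 4))) # MAF = 4/80 = 0.05
  snps2 <- data.frame(snp_id = "edge", chrom = "1", pos = 1L,
                      allele1 = "A", allele2 = "G", stringsAsFactors = FALSE)
  expect_equal(suppressWarnings(apply_qc(g2, snps2))$report$n_removed_maf, 1)
  # idempotence
  res2 <- apply_qc(res$genotypes, res$snps)
  expect_identical(res2$genotypes, res$genotypes)
  expect_equal(res2$report$n_remaining, res$report$n_remaining)
})

test_that("LD pruning removes one of an identical pair and keeps independents", {
  set.seed(4)
  base <- rbinom(80, 2, 0.4)
  g <- cbind(s1 = base, s2 = base, s3 = rbinom(80, 2, 0.4))
  storage.mode(g) <- "integer"
  snps <- data.frame(snp_id = colnames(g), chrom = "1", pos = c(10L, 20L, 30L),
                     allele1 = "A", allele2 = "G", stringsAsFactors = FALSE)
  kept <- ld_prune(g, snps)
  expect_equal(kept, c("s1", "s3")) # equal MAF: later position goes

  ind <- sapply(runif(12, 0.2, 0.5), function(f) rbinom(200, 2, f))
  colnames(ind) <- sprintf("i%02d", 1:12)
  storage.mode(ind) <- "integer"
  snps_i <- data.frame(snp_id = colnames(ind), chrom = "1", pos = 1:12 * 5L,
                       allele1 = "A", allele2 = "G", stringsAsFactors = FALSE)
  expect_equal(ld_prune(ind, snps_i), colnames(ind))
  expect_error(ld_prune(ind, snps_i[12:1, ]), "ordered")
})

test_that("windowed pruner agrees with the exhaustive all-pairs oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 120
    cols <- list()
    base1 <- rbinom(n, 2, 0.35)
    base2 <- rbinom(n, 2, 0.45)
    base3 <- rbinom(n, 2, 0.25)
    mk_corr <- function(b) { # correlated companion: copy with a few flips
      x <- b
      i <- sample(n, 6)
      x[i] <- rbinom(6, 2, 0.35)
      x
    }
    g <- cbind(base1, mk_corr(base1), base2, mk_corr(base2), base3, mk_corr(base3),
               sapply(runif(6, 0.2, 0.5), function(f) rbinom(n, 2, f)))
    colnames(g) <- sprintf("p%02d", 1:12)
    storage.mode(g) <- "integer"
    snps <- data.frame(snp_id = colnames(g), chrom = "1", pos = 1:12 * 7L,
                       allele1 = "A", allele2 = "G", stringsAsFactors = FALSE)
    expect_equal(ld_prune(g, snps), oracle_prune_all_pairs(g, snps))
  }
})

test_that("no surviving window pair exceeds the r2 ceiling after pruning", {
  co <- simulate_cohort(sim_config(n_individuals = 150, n_snps = 120,
                                   n_causal = 10, within_block_r = 0.9,
                                   seed = 17))
  cfg <- qc_config()
  kept <- ld_prune(co$genotypes, co$snps, cfg)
  g <- co$genotypes[, kept, drop = FALSE]
  g <- apply(g, 2, function(x) { x[is.na(x)] <- mean(x, na.rm = TRUE); x })
  for (s in seq(1, ncol(g) - 1, by = cfg$ld_step)) {
    w <- s:min(s + cfg$ld_window - 1, ncol(g))
    r2 <- suppressWarnings(cor(g[, w]))^2
    diag(r2) <- 0
    r2[!is.finite(r2)] <- 0
    expect_lte(max(r2), cfg$ld_r2_max)
  }
})
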