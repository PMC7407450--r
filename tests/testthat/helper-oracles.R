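# Independent oracles used across tests. Each is written as plain
# brute-force arithmetic, deliberately sharing no code with the package
# implementation it checks.

# straight-line 2-bit PLINK decoder: walks bytes and bit-pairs one at a time
oracle_decode_bed <- function(path, n, p) {
  raw <- readBin(path, what = "raw", n = file.size(path))
  stopifnot(raw[1] == as.raw(0x6c), raw[2] == as.raw(0x1b), raw[3] == as.raw(0x01))
  payload <- raw[-(1:3)]
  bps <- ceiling(n / 4)
  out <- matrix(NA_integer_, n, p)
  for (j in seq_len(p)) {
    snp_bytes <- payload[((j - 1) * bps + 1):(j * bps)]
    bits <- as.integer(rawToBits(snp_bytes)) # little-endian within byte
    for (i in seq_len(n)) {
      b0 <- bits[2 * i - 1]
      b1 <- bits[2 * i]
      code <- b0 + 2L * b1
      out[i, j] <- if (code == 0L) 2L else if (code == 1L) NA_integer_
                   else if (code == 2L) 1L else 0L
    }
  }
  out
}

# exhaustive pairwise Mann-Whitney AUC
oracle_auc_pairs <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels != 1]
  conc <- 0
  ties <- 0
  for (a in cs) {
    conc <- conc + sum(a > ct)
    ties <- ties + sum(a == ct)
  }
  (conc + 0.5 * ties) / (length(cs) * length(ct))
}

# HWE exact test by the heterozygote-count recurrence (Wigginton-style):
# enumerates the full conditional distribution without factorials
oracle_hwe_distribution <- function(n, nA) {
  na <- 2L * n - nA
  h_max <- min(nA, na)
  if (h_max %% 2L != nA %% 2L) h_max <- h_max - 1L
  h_seq <- seq(nA %% 2L, h_max, by = 2L)
  pr <- numeric(length(h_seq))
  pr[length(pr)] <- 1
  # downward recurrence: P(h-2)/P(h) = h(h-1) / (4 (nAA+1)(naa+1))
  if (length(h_seq) > 1) {
    for (k in rev(seq_len(length(h_seq) - 1))) {
      h <- h_seq[k + 1]
      nAA <- (nA - h) / 2
      naa <- (na - h) / 2
      pr[k] <- pr[k + 1] * h * (h - 1) / (4 * (nAA + 1) * (naa + 1))
    }
  }
  list(het = h_seq, prob = pr / sum(pr))
}

oracle_hwe_p <- function(nAA, nAa, naa) {
  d <- oracle_hwe_distribution(nAA + nAa + naa, 2L * nAA + nAa)
  p0 <- d$prob[match(nAa, d$het)]
  min(1, sum(d$prob[d$prob <= p0 * (1 + 1e-12)]))
}

# exhaustive all-pairs LD pruner (no windows; valid when all SNPs fit one
# window): repeatedly removes the lower-MAF member of the worst r^2 pair
oracle_prune_all_pairs <- function(genotypes, snps, r2_max = 0.7) {
  x <- genotypes
  storage.mode(x) <- "double"
  for (j in seq_len(ncol(x))) {
    m <- mean(x[, j], na.rm = TRUE)
    x[is.na(x[, j]), j] <- m
  }
  maf <- pmin(colMeans(x) / 2, 1 - colMeans(x) / 2)
  alive <- rep(TRUE, ncol(x))
  repeat {
    idx <- which(alive)
    if (length(idx) < 2) break
    best <- NULL
    best_r2 <- r2_max
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (b <= a) next
        r <- suppressWarnings(cor(x[, idx[a]], x[, idx[b]]))
        if (!is.finite(r)) next
        if (r^2 > best_r2) {
          best_r2 <- r^2
          best <- c(idx[a], idx[b])
        }
      }
    }
    if (is.null(best)) break
    drop <- if (maf[best[1]] < maf[best[2]]) best[1]
            else if (maf[best[2]] < maf[best[1]]) best[2]
            else max(best)
    alive[drop] <- FALSE
  }
  snps$snp_id[alive]
}

# 2-D quadrature over (mu, alpha) for a single-SNP probit posterior with
# alpha ~ N(0, v0) and a flat prior on mu (model residual variance 1)
oracle_probit_quadrature <- function(g_centered, y, v0,
                                     mu_grid = seq(-3, 3, length.out = 121),
                                     a_grid = seq(-3, 3, length.out = 121)) {
  logpost <- outer(mu_grid, a_grid, function(mu, a) {
    ll <- vapply(seq_along(mu), function(k) {
      eta <- mu[k] + g_centered * a[k]
      sum(y * pnorm(eta, log.p = TRUE) +
            (1 - y) * pnorm(-eta, log.p = TRUE))
    }, numeric(1))
    ll + dnorm(a, 0, sqrt(v0), log = TRUE)
  })
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  list(alpha_mean = sum(t(w) * a_grid),
       mu_mean = sum(w * mu_grid))
}
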