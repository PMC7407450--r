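#' Marker quality-control configuration
#'
#' Defaults reproduce a standard PLINK-style filter set for a dense canine
#' SNP panel: exclude SNPs with minor allele frequency less than *or equal
#' to* 0.05, call rate less than or equal to 0.95, or exact Hardy-Weinberg
#' p below 1e-7; prune LD at r^2 > 0.7 in 50-SNP windows advanced 5 SNPs at
#' a time (the `--indep-pairwise 50 5 0.7` idiom).
#'
#' @param maf_exclude_max exclude SNPs with MAF `<=` this value (inclusive).
#' @param callrate_min exclude SNPs with call rate `<=` this value.
#' @param hwe_p_min exclude SNPs with exact HWE p `<` this value.
#' @param ld_r2_max prune one SNP of any within-window pair with dosage
#'   r^2 `>` this value.
#' @param ld_window window size in SNPs.
#' @param ld_step window step in SNPs.
#' @return list of class `qc_config`.
#' @export
qc_config <- function(maf_exclude_max = 0.05, callrate_min = 0.95,
                      hwe_p_min = 1e-7, ld_r2_max = 0.7,
                      ld_window = 50, ld_step = 5) {
  stopifnot(maf_exclude_max >= 0, maf_exclude_max < 0.5,
            callrate_min >= 0, callrate_min <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1,
            ld_r2_max > 0, ld_r2_max <= 1,
            ld_window >= 2, ld_step >= 1)
  structure(list(maf_exclude_max = maf_exclude_max, callrate_min = callrate_min,
                 hwe_p_min = hwe_p_min, ld_r2_max = ld_r2_max,
                 ld_window = ld_window, ld_step = ld_step),
            class = "qc_config")
}

#' Per-SNP minor allele frequency
#'
#' Computed over non-missing calls; dosages are assumed to count the minor
#' allele, but frequencies above 0.5 (possible after subsetting samples)
#' are folded back, so the result is always in `[0, 0.5]`. All-missing SNPs
#' get `NA`.
#'
#' @param genotypes dosage matrix (0/1/2/`NA`).
#' @return numeric vector of MAFs, one per SNP.
#' @export
snp_maf <- function(genotypes) {
  f <- colMeans(genotypes, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  pmin(f, 1 - f)
}

#' Per-SNP call rate
#' @param genotypes dosage matrix.
#' @return fraction of non-missing calls per SNP.
#' @export
snp_call_rate <- function(genotypes) {
  colMeans(!is.na(genotypes))
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Two-sided exact p-value conditional on the observed allele counts:
#' all heterozygote counts compatible with the allele totals are
#' enumerated, and p is the sum of the probabilities of those configurations
#' no more probable than the observed one (no mid-p correction). Vectorized
#' over genotype-count triples.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (homozygous major, heterozygous,
#'   homozygous minor); recycled to common length.
#' @return p-values in (0, 1].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  args <- cbind(n_AA, n_Aa, n_aa)
  if (any(args < 0) || any(args != floor(args))) {
    stop("genotype counts must be non-negative integers")
  }
  apply(args, 1, function(g) hwe_exact_p1(g[1], g[2], g[3]))
}

# distribution of the heterozygote count given allele totals, in closed
# log-gamma form:
#   P(nAa | n, nA) = n! / (nAA! nAa! naa!) * 2^nAa * nA! na! / (2n)!
hwe_het_distribution <- function(n, nA) {
  na <- 2L * n - nA
  h_min <- if (nA %% 2L == 0L) 0L else 1L
  h <- seq(h_min, min(nA, na), by = 2L)
  nAA <- (nA - h) / 2
  naa <- (na - h) / 2
  lp <- lgamma(n + 1) - lgamma(nAA + 1) - lgamma(h + 1) - lgamma(naa + 1) +
    h * log(2) + lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  pr <- exp(lp - max(lp))
  list(het = h, prob = pr / sum(pr))
}

hwe_exact_p1 <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  if (n < 1) stop("total genotype count must be >= 1")
  nA <- 2L * nAA + nAa
  d <- hwe_het_distribution(n, nA)
  p_obs <- d$prob[match(nAa, d$het)]
  # tolerance guards ties against floating-point noise (as in common
  # exact-test implementations)
  min(1, sum(d$prob[d$prob <= p_obs * (1 + 1e-12)]))
}

#' Apply marker quality control
#'
#' Filters are applied in a fixed order -- call rate, then MAF, then exact
#' HWE -- so each removed SNP is attributed to exactly one filter. Both the
#' MAF and call-rate thresholds are inclusive exclusions (`<=`), the HWE
#' threshold exclusive (`<`).
#'
#' @param genotypes dosage matrix.
#' @param snps SNP table aligned with the columns of `genotypes`.
#' @param cfg a [qc_config()].
#' @return list with `genotypes`, `snps` (survivors, `maf` refreshed) and
#'   `report`, a list with per-filter removal counts and id lists.
#' @export
apply_qc <- function(genotypes, snps, cfg = qc_config()) {
  stopifnot(ncol(genotypes) == nrow(snps))
  p <- ncol(genotypes)
  ids <- snps$snp_id

  callrate <- snp_call_rate(genotypes)
  rm_call <- callrate <= cfg$callrate_min

  maf <- snp_maf(genotypes)
  rm_maf <- !rm_call & (is.na(maf) | maf <= cfg$maf_exclude_max)

  candidate <- !(rm_call | rm_maf)
  hwe_p <- rep(NA_real_, p)
  if (any(candidate)) {
    counts <- vapply(which(candidate), function(j) {
      d <- genotypes[, j]
      c(sum(d == 0L, na.rm = TRUE), sum(d == 1L, na.rm = TRUE),
        sum(d == 2L, na.rm = TRUE))
    }, numeric(3))
    hwe_p[candidate] <- hwe_exact_p(counts[1, ], counts[2, ], counts[3, ])
  }
  rm_hwe <- candidate & !is.na(hwe_p) & hwe_p < cfg$hwe_p_min

  keep <- !(rm_call | rm_maf | rm_hwe)
  if (!any(keep)) warning("no SNPs survive quality control")

  out_snps <- snps[keep, , drop = FALSE]
  out_geno <- genotypes[, keep, drop = FALSE]
  out_snps$maf <- snp_maf(out_geno)
  rownames(out_snps) <- NULL

  report <- list(
    n_input = p,
    n_removed_callrate = sum(rm_call),
    n_removed_maf = sum(rm_maf),
    n_removed_hwe = sum(rm_hwe),
    n_remaining = sum(keep),
    removed_callrate = ids[rm_call],
    removed_maf = ids[rm_maf],
    removed_hwe = ids[rm_hwe],
    kept = ids[keep]
  )
  list(genotypes = out_geno, snps = out_snps, report = report)
}

#' Windowed LD pruning
#'
#' Slides a window of `ld_window` SNPs along each chromosome in steps of
#' `ld_step` SNPs; inside each window, while any pair of surviving SNPs has
#' squared Pearson correlation of (mean-imputed) dosages above `ld_r2_max`,
#' the member of the worst pair with the lower MAF is removed (ties:
#' the later genomic position goes).
#'
#' @param genotypes dosage matrix.
#' @param snps SNP table, ordered by (chrom, pos).
#' @param cfg a [qc_config()].
#' @return character vector of kept SNP ids, in genomic order.
#' @export
ld_prune <- function(genotypes, snps, cfg = qc_config()) {
  stopifnot(ncol(genotypes) == nrow(snps))
  ord <- order(snps$chrom, snps$pos)
  if (!identical(ord, seq_len(nrow(snps)))) {
    stop("SNP table must be ordered by (chromosome, position)")
  }
  maf <- snp_maf(genotypes)
  keep <- rep(TRUE, nrow(snps))
  for (chr in unique(snps$chrom)) {
    idx <- which(snps$chrom == chr)
    len <- length(idx)
    starts <- seq(1L, max(1L, len - 1L), by = cfg$ld_step)
    for (s in starts) {
      w <- idx[s:min(s + cfg$ld_window - 1L, len)]
      w <- w[keep[w]]
      if (length(w) < 2) next
      x <- impute_mean(genotypes[, w, drop = FALSE])
      r2 <- suppressWarnings(stats::cor(x))^2
      r2[!is.finite(r2)] <- 0
      diag(r2) <- 0
      while (max(r2) > cfg$ld_r2_max) {
        worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        a <- w[worst[1]]; b <- w[worst[2]]
        drop_snp <- if (is.na(maf[a]) || is.na(maf[b])) {
          max(a, b)
        } else if (maf[a] < maf[b]) a
        else if (maf[b] < maf[a]) b
        else max(a, b) # equal MAF: drop the later position
        keep[drop_snp] <- FALSE
        di <- match(drop_snp, w)
        r2[di, ] <- 0
        r2[, di] <- 0
      }
    }
  }
  snps$snp_id[keep]
}
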