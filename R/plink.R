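#' Read a PLINK binary fileset
#'
#' Decodes a SNP-major PLINK `.bed`/`.bim`/`.fam` fileset into a dosage
#' matrix plus SNP and sample tables. Genotypes are re-oriented so that
#' dosages count the *minor* allele at every SNP (ties at frequency 0.5 keep
#' the allele-1 orientation of the file); the returned SNP table reflects any
#' allele swap performed during re-orientation, so `allele1` is always the
#' counted allele.
#'
#' @param prefix Path prefix of the fileset; `<prefix>.bed`, `<prefix>.bim`
#'   and `<prefix>.fam` must all exist.
#' @return A list with components:
#'   \describe{
#'     \item{genotypes}{integer matrix, samples x SNPs, entries 0/1/2 (minor
#'       allele count) or `NA` for missing; dimnames are sample and SNP ids.}
#'     \item{snps}{data.frame with `snp_id`, `chrom`, `pos`, `allele1`,
#'       `allele2`, `maf` (computed over non-missing calls).}
#'     \item{samples}{data.frame with `sample_id`, `phenotype` (0 control /
#'       1 case / `NA`), `sex` (`"female"`/`"male"`/`NA`), and `NA` columns
#'       `neutered`, `weight` to be filled by [read_covariates()].}
#'   }
#' @seealso [write_plink()], [read_covariates()]
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop("missing file: ", f)
  }

  snps <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                            colClasses = c("character", "character", "character",
                                           "integer", "character", "character"))
  names(snps) <- c("chrom", "snp_id", "cm", "pos", "allele1", "allele2")
  snps$cm <- NULL
  if (anyDuplicated(snps$snp_id)) stop("duplicate SNP ids in ", bim)

  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(fam_df) < 6) stop("malformed .fam file: ", fam)
  names(fam_df)[1:6] <- c("fid", "sample_id", "pat", "mat", "sex_code", "phen_code")
  if (anyDuplicated(fam_df$sample_id)) stop("duplicate sample ids in ", fam)

  n <- nrow(fam_df)
  p <- nrow(snps)
  bytes_per_snp <- ceiling(n / 4)

  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3L ||
      raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("unsupported format: not a PLINK .bed file (bad magic bytes)")
  }
  if (raw[3] != as.raw(0x01)) {
    stop("unsupported format: only SNP-major .bed (mode byte 0x01) is supported")
  }
  payload <- raw[-(1:3)]
  if (length(payload) != bytes_per_snp * p) {
    stop("corrupt fileset: .bed payload is ", length(payload),
         " bytes, expected ", bytes_per_snp * p)
  }

  dos <- decode_bed_payload(payload, n, p)
  dimnames(dos) <- list(fam_df$sample_id, snps$snp_id)

  # re-orient to minor-allele dosage; ties (freq exactly 0.5) keep allele1
  freq1 <- colMeans(dos, na.rm = TRUE) / 2
  freq1[is.nan(freq1)] <- NA_real_
  flip <- !is.na(freq1) & freq1 > 0.5
  if (any(flip)) {
    dos[, flip] <- 2L - dos[, flip]
    a1 <- snps$allele1
    snps$allele1[flip] <- snps$allele2[flip]
    snps$allele2[flip] <- a1[flip]
    freq1[flip] <- 1 - freq1[flip]
  }
  snps$maf <- freq1

  samples <- data.frame(
    sample_id = fam_df$sample_id,
    phenotype = ifelse(fam_df$phen_code == 2, 1L,
                       ifelse(fam_df$phen_code == 1, 0L, NA_integer_)),
    sex = ifelse(fam_df$sex_code == 1, "male",
                 ifelse(fam_df$sex_code == 2, "female", NA_character_)),
    neutered = NA_character_,
    weight = NA_real_,
    stringsAsFactors = FALSE
  )

  list(genotypes = dos, snps = snps, samples = samples)
}

# 2-bit PLINK codes, within-byte order LSB first:
#   00 -> 2 copies of allele1, 01 -> missing, 10 -> 1 copy, 11 -> 0 copies
decode_bed_payload <- function(payload, n, p) {
  b <- as.integer(payload)
  code_to_dos <- c(2L, NA_integer_, 1L, 0L) # indexed by code + 1
  bytes_per_snp <- ceiling(n / 4)
  out <- matrix(NA_integer_, nrow = 4 * bytes_per_snp, ncol = p)
  for (pos in 0:3) {
    codes <- bitwAnd(bitwShiftR(b, 2L * pos), 3L)
    out[seq(pos + 1L, 4L * bytes_per_snp, by = 4L), ] <- code_to_dos[codes + 1L]
  }
  out[seq_len(n), , drop = FALSE]
}

#' Write a PLINK binary fileset
#'
#' Inverse of [read_plink()]: dosages are interpreted as counts of
#' `snps$allele1` and encoded SNP-major. When the dosage matrix is in
#' minor-allele orientation (as produced by [read_plink()] or
#' [simulate_cohort()]), `read_plink(write_plink(...))` round-trips the
#' cohort exactly.
#'
#' @param genotypes integer matrix samples x SNPs of 0/1/2/`NA`.
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos`, `allele1`,
#'   `allele2` aligned with the columns of `genotypes`.
#' @param samples data.frame with columns `sample_id`, `phenotype`, `sex`
#'   aligned with the rows of `genotypes`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly; side effect is the three files on disk.
#' @export
write_plink <- function(genotypes, snps, samples, prefix) {
  n <- nrow(genotypes)
  p <- ncol(genotypes)
  if (nrow(snps) != p) stop("dimension mismatch: ", p, " genotype columns vs ",
                            nrow(snps), " SNP table rows")
  if (nrow(samples) != n) stop("dimension mismatch: ", n, " genotype rows vs ",
                               nrow(samples), " sample table rows")
  bad <- !(genotypes %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype entries must be 0, 1, 2 or NA")

  bytes_per_snp <- ceiling(n / 4)
  # dosage (allele1 count) -> 2-bit code: 2->00, NA->01, 1->10, 0->11
  dos_to_code <- function(d) {
    code <- integer(length(d))
    code[is.na(d)] <- 1L
    code[!is.na(d) & d == 1L] <- 2L
    code[!is.na(d) & d == 0L] <- 3L
    code # d == 2 stays 0
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  if (p > 0L) {
    codes <- matrix(0L, nrow = 4L * bytes_per_snp, ncol = p)
    codes[seq_len(n), ] <- apply(genotypes, 2, dos_to_code)
    # pad rows beyond n stay code 0 (homozygous allele1); PLINK ignores them
    bytes <- codes[seq(1, 4 * bytes_per_snp, by = 4), , drop = FALSE] +
      bitwShiftL(codes[seq(2, 4 * bytes_per_snp, by = 4), , drop = FALSE], 2L) +
      bitwShiftL(codes[seq(3, 4 * bytes_per_snp, by = 4), , drop = FALSE], 4L) +
      bitwShiftL(codes[seq(4, 4 * bytes_per_snp, by = 4), , drop = FALSE], 6L)
    writeBin(as.raw(bytes), con)
  }

  bim <- data.frame(chrom = snps$chrom, snp_id = snps$snp_id,
                    cm = rep(0L, p), pos = snps$pos,
                    a1 = snps$allele1, a2 = snps$allele2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  sex_code <- ifelse(is.na(samples$sex), 0L,
                     ifelse(samples$sex == "male", 1L, 2L))
  phen_code <- ifelse(is.na(samples$phenotype), -9L,
                      ifelse(samples$phenotype == 1L, 2L, 1L))
  fam <- data.frame(fid = samples$sample_id, iid = samples$sample_id,
                    pat = 0L, mat = 0L, sex = sex_code, phen = phen_code)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a covariate table and merge it into a sample table
#'
#' The covariate file is delimited text (tab, comma or whitespace) with a
#' header containing at least `sample_id`, `sex`, `neutered`, `weight`.
#' Covariate rows whose `sample_id` does not occur in `samples` are dropped
#' with a warning; samples without a covariate row keep `NA` covariates.
#'
#' @param path covariate file path.
#' @param samples sample table as returned by [read_plink()].
#' @return `samples` with `sex`, `neutered`, `weight` filled in; row order
#'   is preserved.
#' @export
read_covariates <- function(path, samples) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
  cov <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  required <- c("sample_id", "sex", "neutered", "weight")
  missing_cols <- setdiff(required, names(cov))
  if (length(missing_cols)) {
    stop("covariate file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  cov$sample_id <- as.character(cov$sample_id)
  unmatched <- setdiff(cov$sample_id, samples$sample_id)
  if (length(unmatched)) {
    warning(length(unmatched), " covariate row(s) with unknown sample_id dropped: ",
            paste(utils::head(unmatched, 5), collapse = ", "))
    cov <- cov[cov$sample_id %in% samples$sample_id, , drop = FALSE]
  }
  idx <- match(samples$sample_id, cov$sample_id)
  hit <- !is.na(idx)
  samples$sex[hit] <- cov$sex[idx[hit]]
  samples$neutered[hit] <- cov$neutered[idx[hit]]
  samples$weight[hit] <- cov$weight[idx[hit]]
  if (any(!is.na(samples$weight) & samples$weight <= 0)) {
    stop("weights must be positive")
  }
  samples
}

#' Write a covariate table
#'
#' Companion to [read_covariates()]: writes `sample_id`, `sex`, `neutered`
#' and `weight` as tab-separated text.
#'
#' @param samples sample table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(samples, path) {
  utils::write.table(
    samples[, c("sample_id", "sex", "neutered", "weight")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

# mean-impute missing dosages column-wise; `means` (training-column means)
# may be supplied so test data are imputed with training statistics
impute_mean <- function(genotypes, means = NULL) {
  x <- genotypes
  storage.mode(x) <- "double"
  if (is.null(means)) {
    means <- colMeans(x, na.rm = TRUE)
    means[is.nan(means)] <- 0
  }
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- means[idx[, 2]]
  }
  attr(x, "imputation_means") <- means
  x
}
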