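# PLINK 1 binary codec and the QC / phenotype-transformation operations.
#
# bed format (v1.00, SNP-major): magic bytes 0x6c 0x1b, mode byte 0x01,
# then ceil(n/4) bytes per SNP, two bits per genotype, sample order along
# the byte from the low bits:
#   00 = homozygous A1, 10 = heterozygous, 11 = homozygous A2, 01 = missing.
# No installed package reads this format, so the codec is implemented here
# and exercised by round-trip tests.

#' Write genotypes as PLINK bed/bim/fam
#'
#' The stored A1 allele is the package's counted (minor) allele, so the
#' A1 dosage equals the internal dosage.
#'
#' @param G a [genotype_matrix()].
#' @param stem path stem; `.bed`, `.bim`, `.fam` are appended.
#' @param pedigree optional pedigree table supplying fam columns
#'   (father, mother, sex); otherwise placeholders are written.
#' @return invisibly, the bed path.
#' @export
write_plink <- function(G, stem, pedigree = NULL) {
  dos <- G$dosage
  n <- nrow(dos); m <- ncol(dos)
  bim <- data.frame(chr = G$snps$chr, id = G$snps$snp_id, cm = 0,
                    pos = G$snps$pos, a1 = G$snps$allele_minor,
                    a2 = G$snps$allele_major)
  utils::write.table(bim, paste0(stem, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (is.null(pedigree)) {
    fam <- data.frame(fid = G$samples, iid = G$samples, father = 0,
                      mother = 0, sex = 0, pheno = -9)
  } else {
    ped <- pedigree[match(G$samples, pedigree$iid), ]
    fam <- data.frame(fid = ped$fid %||% ped$iid, iid = ped$iid,
                      father = ifelse(is.na(ped$father), 0, ped$father),
                      mother = ifelse(is.na(ped$mother), 0, ped$mother),
                      sex = ped$sex, pheno = -9)
  }
  utils::write.table(fam, paste0(stem, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  # code per genotype: dosage of A1 -> bit pair
  code <- matrix(1L, n, m)                       # 01 = missing
  code[!is.na(dos) & dos == 2] <- 3L             # 11 stored; see flip below
  code[!is.na(dos) & dos == 1] <- 2L
  code[!is.na(dos) & dos == 0] <- 0L
  # PLINK: 00 = hom A1 (dosage 2 of A1), 11 = hom A2 (dosage 0)
  code[!is.na(dos) & dos == 2] <- 0L
  code[!is.na(dos) & dos == 0] <- 3L
  bpS <- ceiling(n / 4)
  pad <- bpS * 4L
  codep <- rbind(code, matrix(0L, pad - n, m))
  i4 <- matrix(codep, nrow = 4L)                  # 4 genotypes per byte
  bytes <- as.raw(i4[1, ] + i4[2, ] * 4L + i4[3, ] * 16L + i4[4, ] * 64L)
  con <- file(paste0(stem, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)
  invisible(paste0(stem, ".bed"))
}

#' Read PLINK bed/bim/fam into a genotype matrix
#'
#' Dosages are re-oriented so that they count the empirically minor
#' allele (sample frequency <= 0.5; ties broken by lexicographic allele
#' order), regardless of which allele the file stores as A1. Missing
#' calls are preserved as `NA`.
#'
#' @param stem path stem of the triplet, or the `.bed` path itself.
#' @return a [genotype_matrix()].
#' @export
read_plink <- function(stem) {
  stem <- sub("\\.bed$", "", stem)
  bim <- utils::read.table(paste0(stem, ".bim"), header = FALSE,
                           col.names = c("chr", "id", "cm", "pos", "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paste0(stem, ".fam"), header = FALSE,
                           colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(stem, ".bed"), "raw",
                 n = 3 + ceiling(n / 4) * m)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop_format("not a PLINK bed file (bad magic bytes)")
  if (raw[3] != as.raw(0x01))
    stop_format("only SNP-major bed files are supported")
  body <- raw[-(1:3)]
  bpS <- ceiling(n / 4)
  if (length(body) != bpS * m)
    stop_format("bed size inconsistent with bim/fam dimensions")
  v <- as.integer(body)
  # unpack 4 two-bit codes per byte
  codes <- rbind(v %% 4L, (v %/% 4L) %% 4L, (v %/% 16L) %% 4L, v %/% 64L)
  codes <- matrix(codes, nrow = bpS * 4L)[seq_len(n), , drop = FALSE]
  dos <- matrix(NA_real_, n, m)
  dos[codes == 0L] <- 2   # hom A1
  dos[codes == 2L] <- 1
  dos[codes == 3L] <- 0
  # orient to minor allele
  freq <- colMeans(dos, na.rm = TRUE) / 2
  a_minor <- bim$a1; a_major <- bim$a2
  flip <- !is.na(freq) &
    (freq > 0.5 | (freq == 0.5 & a_major < a_minor))
  if (any(flip)) {
    dos[, flip] <- 2 - dos[, flip]
    tmp <- a_minor[flip]; a_minor[flip] <- a_major[flip]; a_major[flip] <- tmp
  }
  snps <- data.frame(snp_id = bim$id, chr = as.integer(bim$chr),
                     pos = bim$pos, allele_minor = a_minor,
                     allele_major = a_major, stringsAsFactors = FALSE)
  genotype_matrix(dos, snps, samples = fam[[2]])
}

#' Minor-allele-frequency filter
#'
#' Removal is strict: a SNP is dropped when maf < `threshold`, so a SNP
#' at exactly the threshold is retained. MAF is computed on non-missing
#' calls.
#'
#' @param G a [genotype_matrix()] or dosage matrix.
#' @param threshold maf cutoff in `[0, 0.5]` (default 0.01).
#' @return integer vector of retained SNP indices, with attribute
#'   `"n_removed"`.
#' @export
filter_maf <- function(G, threshold = 0.01) {
  if (threshold < 0 || threshold > 0.5)
    stop_config("maf threshold must be in [0, 0.5]")
  maf <- compute_maf(G)
  maf <- pmin(maf, 1 - maf)
  keep <- which(!is.na(maf) & maf >= threshold)
  attr(keep, "n_removed") <- length(maf) - length(keep)
  keep
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test by full enumeration of heterozygote counts
#' conditional on the observed allele counts: the p-value is the total
#' probability of all heterozygote configurations no more probable than
#' the observed one (no mid-p adjustment). Vectorized over SNPs.
#'
#' @param n_hom_major,n_het,n_hom_minor genotype counts (recycled to a
#'   common length).
#' @return p-values in (0, 1]; monomorphic SNPs give exactly 1.
#' @export
hwe_test <- function(n_hom_major, n_het, n_hom_minor) {
  nn <- cbind(n_hom_major, n_het, n_hom_minor)
  if (any(nn < 0)) stop_data("genotype counts must be non-negative")
  if (any(rowSums(nn) < 1)) stop_data("all genotype counts are zero")
  apply(nn, 1L, function(x) hwe_exact_one(x[1], x[2], x[3]))
}

# Conditional distribution of the heterozygote count given allele
# counts, by the standard recurrence; p = sum of probabilities <= that
# of the observed configuration (with a small tolerance for ties).
hwe_exact_one <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa            # rarer-or-not allele count
  n_A <- 2 * n_AA + n_Aa
  if (n_a > n_A) { tmp <- n_a; n_a <- n_A; n_A <- tmp }
  if (n_a == 0) return(1)
  hets <- seq(n_a %% 2, n_a, by = 2)
  probs <- numeric(length(hets))
  # recur outward from the modal heterozygote count so that all stored
  # ratios are <= 1 (no overflow for large samples)
  mid <- round(n_a * n_A / (n_a + n_A))
  if (mid %% 2 != n_a %% 2) mid <- mid + 1L
  mid <- min(max(mid, hets[1]), n_a)
  k0 <- match(mid, hets)
  probs[k0] <- 1
  if (k0 > 1) for (k in (k0 - 1L):1L) {
    h <- hets[k + 1L]               # moving from h to h - 2
    hom_r <- (n_a - h) / 2
    hom_c <- (n_A - h) / 2
    probs[k] <- probs[k + 1L] * h * (h - 1) /
      (4 * (hom_r + 1) * (hom_c + 1))
  }
  if (k0 < length(hets)) for (k in (k0 + 1L):length(hets)) {
    h <- hets[k - 1L]               # moving from h to h + 2
    hom_r <- (n_a - h) / 2
    hom_c <- (n_A - h) / 2
    probs[k] <- probs[k - 1L] * 4 * hom_r * hom_c /
      ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  obs <- match(n_Aa, hets)
  min(1, sum(probs[probs <= probs[obs] * (1 + 1e-10)]))
}

#' Joint MAF + HWE quality control
#'
#' Applies the maf filter first; HWE is then evaluated only on the
#' maf-passing SNPs (mirroring the usual QC ordering), dropping SNPs
#' with exact-test p below `hwe_p_min`.
#'
#' @param G a [genotype_matrix()].
#' @param maf_min maf threshold (default 0.01).
#' @param hwe_p_min HWE p-value threshold (default 1e-6).
#' @return list: `genotypes` (filtered [genotype_matrix()]), `keep`
#'   (retained indices into the input), and `report` (`n_input`,
#'   `n_removed_maf`, `n_removed_hwe`, `n_retained`).
#' @export
qc_genotypes <- function(G, maf_min = 0.01, hwe_p_min = 1e-6) {
  m <- ncol(G$dosage)
  keep_maf <- filter_maf(G, maf_min)
  dos <- G$dosage[, keep_maf, drop = FALSE]
  n_AA <- colSums(dos == 0, na.rm = TRUE)
  n_Aa <- colSums(dos == 1, na.rm = TRUE)
  n_aa <- colSums(dos == 2, na.rm = TRUE)
  p_hwe <- hwe_test(n_AA, n_Aa, n_aa)
  keep <- keep_maf[p_hwe >= hwe_p_min]
  report <- list(n_input = m,
                 n_removed_maf = m - length(keep_maf),
                 n_removed_hwe = length(keep_maf) - length(keep),
                 n_retained = length(keep))
  list(genotypes = subset_snps(G, keep), keep = keep, report = report)
}

#' Rank-based inverse normal transformation
#'
#' Maps trait values through their fractional ranks onto normal scores:
#' `z_i = qnorm((rank_i - c) / (n - 2c + 1))` with the Blom offset
#' `c = 3/8`. Ties receive average ranks; missing values are excluded
#' from ranking and reinserted as `NA`. Because only ranks enter, any
#' strictly monotone transform of the input yields identical output.
#'
#' @param y numeric trait values (`NA` allowed).
#' @param offset rank offset `c` (default 3/8, the common GWAS choice).
#' @return numeric vector of normal scores, same length/order as `y`.
#' @export
int_transform <- function(y, offset = 3 / 8) {
  ok <- !is.na(y)
  n <- sum(ok)
  if (n < 2) stop_data("need at least 2 non-missing values")
  if (length(unique(y[ok])) < 2)
    stop_data("all values identical: ranks are degenerate")
  r <- rank(y[ok], ties.method = "average")
  z <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out <- rep(NA_real_, length(y))
  out[ok] <- z
  out
}
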