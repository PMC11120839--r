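#' Genotype matrix container
#'
#' Bundles a samples-by-SNPs dosage matrix (minor-allele counts 0/1/2,
#' `NA` allowed) with per-SNP metadata. Dosage columns follow the coding
#' used throughout the package: 2 = homozygote minor allele,
#' 1 = heterozygote, 0 = homozygote major allele.
#'
#' @param dosage numeric matrix, rows = samples, columns = SNPs; values in
#'   `{0, 1, 2, NA}`.
#' @param snps data.frame with one row per SNP and columns `snp_id`,
#'   `chr` (1-22), `pos` (1-based bp), `allele_minor`, `allele_major`.
#'   A `maf` column is recomputed from the data if absent.
#' @param samples character vector of sample identifiers; defaults to the
#'   dosage rownames.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `snps` (metadata incl. `maf`), `samples`.
#' @export
genotype_matrix <- function(dosage, snps, samples = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(samples)) samples <- paste0("ind", seq_len(nrow(dosage)))
  if (nrow(snps) != ncol(dosage))
    stop_format("snps metadata rows must match dosage columns")
  if (length(samples) != nrow(dosage))
    stop_format("sample ids must match dosage rows")
  need <- c("snp_id", "chr", "pos")
  if (!all(need %in% names(snps)))
    stop_format(paste("snps metadata must contain columns:",
                      paste(need, collapse = ", ")))
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0 || max(bad) > 2))
    stop_format("dosages must lie in [0, 2]")
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  rownames(snps) <- NULL
  snps$maf <- compute_maf(dosage)
  rownames(dosage) <- samples
  colnames(dosage) <- snps$snp_id
  structure(list(dosage = dosage, snps = snps, samples = as.character(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs\n",
              nrow(x$dosage), ncol(x$dosage)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$snps$chr), collapse = " ")))
  nmiss <- sum(is.na(x$dosage))
  cat(sprintf("  missing calls: %d (%.3f%%)\n", nmiss,
              100 * nmiss / length(x$dosage)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Minor allele frequency per SNP
#'
#' Frequency of the counted (minor) allele over non-missing calls. Values
#' above 0.5 can occur when the stored orientation disagrees with the
#' sample frequencies; [read_plink()] re-orients so that stored dosages
#' count the empirically minor allele.
#'
#' @param dosage dosage matrix (samples x SNPs) or a `genotype_matrix`.
#' @return numeric vector of allele frequencies of the counted allele.
#' @export
compute_maf <- function(dosage) {
  if (inherits(dosage, "genotype_matrix")) dosage <- dosage$dosage
  colMeans(dosage, na.rm = TRUE) / 2
}

# Subset a genotype_matrix by SNP index (keeps metadata in step).
subset_snps <- function(G, idx) {
  genotype_matrix(G$dosage[, idx, drop = FALSE],
                  G$snps[idx, , drop = FALSE], G$samples)
}
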