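# Gene-level summarization: SNP-to-gene mapping by genomic window,
# sum-of-chi-square gene statistics (optionally LD-aware), and
# hypergeometric gene-set enrichment.

#' Read a gene annotation BED file
#'
#' BED input is 0-based half-open; coordinates are converted to the
#' 1-based inclusive convention used internally. Only the first four
#' columns (chrom, start, end, name) are used.
#'
#' @param path BED file path.
#' @return data.frame (`gene_id`, `chr`, `start`, `end`), 1-based
#'   inclusive.
#' @export
read_gene_bed <- function(path) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop_format("BED file needs at least 4 columns")
  data.frame(gene_id = as.character(bed[[4]]),
             chr = normalize_chr(bed[[1]]),
             start = as.integer(bed[[2]]) + 1L,
             end = as.integer(bed[[3]]),
             stringsAsFactors = FALSE)
}

# "chr1"/"1" labels to integer-ish character; warns once on mixed use.
normalize_chr <- function(x) {
  x <- as.character(x)
  had_prefix <- grepl("^chr", x, ignore.case = TRUE)
  if (any(had_prefix) && !all(had_prefix))
    warning("mixed 'chr' prefix conventions; normalizing")
  sub("^chr", "", x, ignore.case = TRUE)
}

#' Read gene sets from a GMT-like TSV
#'
#' Each line: set name, description, then member genes, tab separated.
#'
#' @param path file path.
#' @return named list of character vectors; names are set names,
#'   attribute `"description"` keeps the second column.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop_format("GMT lines need set, description, >=1 gene")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "description") <- vapply(parts, `[[`, "", 2L)
  sets
}

#' Map SNPs to genes within a window
#'
#' A SNP is assigned to a gene when it lies on the same chromosome
#' within `window` bp of the gene span (boundaries inclusive); a SNP
#' may map to several genes. Interval overlap is computed with
#' GenomicRanges.
#'
#' @param snps SNP metadata (`snp_id`, `chr`, `pos`).
#' @param genes gene table as from [read_gene_bed()].
#' @param window flanking window in bp (default 50000).
#' @return data.frame (`gene_id`, `snp_id`) of all assignments.
#' @export
map_snps_to_genes <- function(snps, genes, window = 50000L) {
  gchr <- normalize_chr(genes$chr)
  schr <- normalize_chr(snps$chr)
  gr_genes <- GenomicRanges::GRanges(
    gchr, IRanges::IRanges(pmax(1L, genes$start - window),
                           genes$end + window))
  gr_snps <- GenomicRanges::GRanges(
    schr, IRanges::IRanges(snps$pos, snps$pos))
  ov <- GenomicRanges::findOverlaps(gr_snps, gr_genes)
  data.frame(gene_id = genes$gene_id[S4Vectors::subjectHits(ov)],
             snp_id = snps$snp_id[S4Vectors::queryHits(ov)],
             stringsAsFactors = FALSE)
}

#' Gene-based sum-of-chi-square test
#'
#' Converts the gene's SNP p-values to upper-tail 1-df chi-square
#' statistics and sums them. Without an LD matrix the sum is referred
#' to a chi-square with n df (valid for independent SNPs). With an LD
#' matrix (pairwise genotype correlation), the null is simulated:
#' multivariate normal draws with that correlation are squared and
#' summed, and the p-value is the (add-one corrected) proportion of
#' draws reaching the observed statistic.
#'
#' @param snp_p numeric vector of SNP p-values in (0, 1]; zeros are
#'   clipped to the smallest positive double with a warning.
#' @param ld optional correlation matrix of the SNP genotypes.
#' @param n_sim Monte-Carlo draws (default 1e5).
#' @param seed RNG seed for the simulation.
#' @return list (`stat`, `n_snps`, `p`, `method`), method one of
#'   `"closed_form"`, `"mvn_sim"`.
#' @export
gene_test <- function(snp_p, ld = NULL, n_sim = 1e5, seed = 1L) {
  if (any(is.na(snp_p)) || any(snp_p < 0) || any(snp_p > 1))
    stop_data("SNP p-values must lie in (0, 1]")
  if (any(snp_p == 0)) {
    warning("p-value of 0 clipped to smallest positive double")
    snp_p[snp_p == 0] <- .Machine$double.xmin
  }
  n <- length(snp_p)
  stat <- sum(stats::qchisq(snp_p, df = 1, lower.tail = FALSE))
  if (is.null(ld)) {
    p <- stats::pchisq(stat, df = n, lower.tail = FALSE)
    method <- "closed_form"
  } else {
    ld <- as.matrix(ld)
    if (!all(dim(ld) == n)) stop_data("ld matrix must be n_snps x n_snps")
    set.seed(seed)
    R <- ld
    diag(R) <- diag(R) + 1e-8
    ch <- tryCatch(chol(R), error = function(e) {
      eg <- eigen(ld, symmetric = TRUE)
      t(eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors)))
    })
    Z <- matrix(stats::rnorm(n_sim * n), n_sim, n) %*% ch
    sims <- rowSums(Z^2)
    p <- (sum(sims >= stat) + 1) / (n_sim + 1)
    method <- "mvn_sim"
  }
  list(stat = stat, n_snps = n, p = max(p, .Machine$double.xmin),
       method = method)
}

#' Gene-level tests for all genes of a module
#'
#' Applies [gene_test()] to every gene of a SNP-to-gene map, pulling
#' each gene's SNP p-values from a GWAS result; when genotypes are
#' supplied the LD-aware null is used.
#'
#' @param mapping data.frame (`gene_id`, `snp_id`) from
#'   [map_snps_to_genes()].
#' @param gwas `gwas_result` providing per-SNP p-values.
#' @param G optional [genotype_matrix()] for LD-aware testing.
#' @param n_sim,seed Monte-Carlo controls for the LD-aware null.
#' @return data.frame (`gene_id`, `n_snps`, `stat`, `p`, `method`)
#'   sorted by p.
#' @export
gene_tests <- function(mapping, gwas, G = NULL, n_sim = 1e5, seed = 1L) {
  pv <- stats::setNames(gwas$p, gwas$snp_id)
  genes <- split(mapping$snp_id, mapping$gene_id)
  res <- lapply(names(genes), function(g) {
    ids <- intersect(genes[[g]], names(pv))
    if (!length(ids)) return(NULL)
    ld <- NULL
    if (!is.null(G) && length(ids) > 1) {
      dos <- impute_mean(G$dosage[, ids, drop = FALSE])
      ld <- suppressWarnings(stats::cor(dos))
      ld[!is.finite(ld)] <- 0; diag(ld) <- 1
    }
    gt <- gene_test(pv[ids], ld = ld, n_sim = n_sim,
                    seed = derive_seed(seed, match(g, names(genes))))
    data.frame(gene_id = g, n_snps = gt$n_snps, stat = gt$stat, p = gt$p,
               method = gt$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$p), , drop = FALSE]
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between the selected
#' genes and each gene set, with Benjamini-Hochberg adjustment across
#' sets. Zero overlap gives p = 1 (the upper tail at zero).
#'
#' @param genes_selected character vector of significant genes.
#' @param gene_sets named list of character vectors (e.g., from
#'   [read_gmt()]).
#' @param background character vector of all testable genes; both the
#'   selection and the sets are intersected with it.
#' @return data.frame (`set`, `n_set`, `overlap`, `expected`, `fold`,
#'   `p`, `p_adj`) sorted by p.
#' @export
enrich <- function(genes_selected, gene_sets, background) {
  background <- unique(background)
  N <- length(background)
  if (N == 0) stop_data("empty background")
  sel <- intersect(unique(genes_selected), background)
  n <- length(sel)
  res <- lapply(names(gene_sets), function(s) {
    set <- intersect(gene_sets[[s]], background)
    K <- length(set)
    k <- length(intersect(sel, set))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    expected <- n * K / N
    data.frame(set = s, n_set = K, overlap = k, expected = expected,
               fold = if (expected > 0) k / expected else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
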