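# Epistatic interaction network: GWAS-based SNP filtering, D'-based LD
# pruning, exhaustive pairwise interaction scan, weighted-network module
# detection in the WGCNA style, and module-eigengene association.

#' Filter SNPs by GWAS p-value
#'
#' Loose marginal screen (default p < 0.01) that selects the candidate
#' SNPs entering the interaction scan, preserving genomic order.
#'
#' @param gwas a `gwas_result` from [score_scan()].
#' @param p_cut inclusion threshold (strict `<`).
#' @return integer indices into the GWAS table / genotype columns.
#' @export
filter_by_gwas <- function(gwas, p_cut = 0.01) {
  idx <- which(gwas$p < p_cut)
  if (!length(idx)) stop_data("no SNPs pass the GWAS filter")
  idx
}

#' Pairwise D' from unphased dosages
#'
#' Haplotype frequencies are estimated by EM over the double-heterozygote
#' phase ambiguity; `D' = |D| / D_max` in `[0, 1]`.
#'
#' @param g1,g2 dosage vectors (minor-allele counts, `NA` dropped
#'   pairwise).
#' @param max_iter,tol EM controls. Non-convergence flags the pair and
#'   returns 0 (treated as unlinked) with attribute `converged = FALSE`.
#' @return scalar D' with attributes `D`, `haplotype_freqs`, `converged`.
#' @export
estimate_dprime <- function(g1, g2, max_iter = 200L, tol = 1e-8) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (stats::var(g1) == 0 || stats::var(g2) == 0)
    stop_data("both SNPs must be polymorphic to estimate D'")
  cnt <- function(a, b) sum(g1 == a & g2 == b)
  n22 <- cnt(2, 2); n21 <- cnt(2, 1); n20 <- cnt(2, 0)
  n12 <- cnt(1, 2); n11 <- cnt(1, 1); n10 <- cnt(1, 0)
  n02 <- cnt(0, 2); n01 <- cnt(0, 1); n00 <- cnt(0, 0)
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  pAB <- pA * pB; pAb <- pA * (1 - pB); paB <- (1 - pA) * pB
  pab <- (1 - pA) * (1 - pB)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    denom <- pAB * pab + pAb * paB
    w <- if (denom > 0) pAB * pab / denom else 0.5
    nAB <- 2 * n22 + n21 + n12 + w * n11
    nAb <- 2 * n20 + n21 + n10 + (1 - w) * n11
    naB <- 2 * n02 + n12 + n01 + (1 - w) * n11
    nab <- 2 * n00 + n10 + n01 + w * n11
    new <- c(nAB, nAb, naB, nab) / (2 * n)
    if (max(abs(new - c(pAB, pAb, paB, pab))) < tol) {
      pAB <- new[1]; pAb <- new[2]; paB <- new[3]; pab <- new[4]
      converged <- TRUE
      break
    }
    pAB <- new[1]; pAb <- new[2]; paB <- new[3]; pab <- new[4]
  }
  pA <- pAB + pAb; pB <- pAB + paB
  D <- pAB - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  dp <- if (!converged || dmax <= 0) 0 else min(1, abs(D) / dmax)
  structure(dp, D = D, haplotype_freqs = c(AB = pAB, Ab = pAb, aB = paB, ab = pab),
            converged = converged)
}

#' Greedy LD pruning into tag SNPs
#'
#' Within each chromosome, scanning left to right: the current block is
#' extended while the candidate SNP has `D' >= dprime_min` with the
#' block's tag and the block holds fewer than `max_block` SNPs; the tag
#' is the leftmost member. Non-tag SNPs are removed.
#'
#' @param G a [genotype_matrix()] (SNPs are sorted internally by
#'   chromosome and position).
#' @param dprime_min D' threshold (default 0.9).
#' @param max_block maximum block size (default 1000).
#' @return integer vector of tag-SNP indices into `G` (genomic order);
#'   attribute `"blocks"` maps every SNP to its block and tag.
#' @export
ld_prune <- function(G, dprime_min = 0.9, max_block = 1000L) {
  snps <- G$snps
  ord <- order(snps$chr, snps$pos)
  dos <- G$dosage
  tags <- integer(0)
  block_id <- integer(nrow(snps))
  bid <- 0L
  for (chr in unique(snps$chr[ord])) {
    idx <- ord[snps$chr[ord] == chr]
    tag <- NA_integer_; size <- 0L
    for (s in idx) {
      linked <- FALSE
      if (!is.na(tag) && size < max_block) {
        dp <- tryCatch(estimate_dprime(dos[, tag], dos[, s]),
                       error = function(e) 0)
        linked <- as.numeric(dp) >= dprime_min
      }
      if (linked) {
        size <- size + 1L
      } else {
        bid <- bid + 1L
        tag <- s; size <- 1L
        tags <- c(tags, s)
      }
      block_id[s] <- bid
    }
  }
  structure(tags, blocks = data.frame(snp = seq_len(nrow(snps)),
                                      block = block_id,
                                      tag = seq_len(nrow(snps)) %in% tags))
}

#' Exhaustive pairwise interaction scan
#'
#' Fits `y = b0 + b1 g_i + b2 g_j + b_ij (g_i g_j) + e` by OLS for every
#' unordered SNP pair and reports the interaction estimate, its
#' t-statistic (n - 4 df) and p-value. Pairs whose design is rank
#' deficient (constant SNP, product collinear with the mains) are
#' flagged with p = 1. Family structure is deliberately not modelled at
#' this stage; it is handled by the module-level GLMM.
#'
#' @param G a [genotype_matrix()] of the pruned candidate SNPs (missing
#'   dosages mean-imputed).
#' @param y_adj adjusted trait: the INT phenotype residualized on age
#'   and sex (see [residualize()]).
#' @return data.frame of class `interaction_result` with columns `i`,
#'   `j` (i < j), `snp_i`, `snp_j`, `beta`, `t`, `p`, `neglogp`,
#'   `flagged`; attribute `n_snps`.
#' @export
pairwise_scan <- function(G, y_adj) {
  dos <- impute_mean(G$dosage)
  n <- nrow(dos)
  if (n <= 4) stop_data("need more than 4 samples for the pair model")
  if (length(y_adj) != n) stop_data("y_adj must match samples")
  if (ncol(dos) < 2) stop_data("need at least 2 SNPs")
  res <- .pair_scan_cpp(dos, as.numeric(y_adj))
  out <- data.frame(i = res$i, j = res$j,
                    snp_i = G$snps$snp_id[res$i], snp_j = G$snps$snp_id[res$j],
                    beta = res$beta, t = res$t, p = res$p,
                    neglogp = ifelse(res$flagged, 0, -log10(pmax(res$p, 1e-300))),
                    flagged = res$flagged, stringsAsFactors = FALSE)
  attr(out, "n_snps") <- ncol(dos)
  attr(out, "snp_ids") <- G$snps$snp_id
  class(out) <- c("interaction_result", "data.frame")
  out
}

#' Residualize a trait on covariates
#'
#' @param y numeric vector; @param X data.frame or matrix of covariates.
#' @return OLS residuals of `y ~ X`.
#' @export
residualize <- function(y, X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  stats::lm.fit(cbind(1, X), y)$residuals
}

#' Chromosome-pair interaction hotspots
#'
#' For every chromosome pair, the `quantile` (default 0.9) of the
#' `-log10 p` of interactions spanning the two chromosomes, min-max
#' rescaled to `[0, 1]` across populated cells (1 = strongest hotspot).
#' If all populated cells are equal the rescaled value is defined as 1.
#' Cells with no estimable pair are `NA`.
#'
#' @param ir an `interaction_result`.
#' @param snps SNP metadata of the scanned panel (`chr` column).
#' @param quantile quantile level within each cell.
#' @param n_chr size of the output matrix (default 22).
#' @return `n_chr` x `n_chr` symmetric matrix in `[0, 1]`.
#' @export
interaction_hotspots <- function(ir, snps, quantile = 0.9, n_chr = 22L) {
  keep <- !ir$flagged
  ci <- snps$chr[ir$i[keep]]; cj <- snps$chr[ir$j[keep]]
  lo <- pmin(ci, cj); hi <- pmax(ci, cj)
  v <- ir$neglogp[keep]
  M <- matrix(NA_real_, n_chr, n_chr,
              dimnames = list(seq_len(n_chr), seq_len(n_chr)))
  agg <- tapply(v, list(factor(lo, levels = 1:n_chr),
                        factor(hi, levels = 1:n_chr)),
                stats::quantile, probs = quantile, names = FALSE)
  M[!is.na(agg)] <- agg[!is.na(agg)]
  filled <- !is.na(M)
  rng <- range(M[filled])
  M[filled] <- if (diff(rng) == 0) 1 else (M[filled] - rng[1]) / diff(rng)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  M
}

#' Per-SNP sum of interaction effect sizes
#'
#' For each SNP, the sum of `-log10 p` over all its estimable pairs:
#' the quantity plotted in a pseudo-Manhattan of interaction burden.
#'
#' @param ir an `interaction_result`.
#' @return numeric vector (one entry per scanned SNP, named by snp id).
#' @export
sum_effect_sizes <- function(ir) {
  k <- attr(ir, "n_snps")
  ids <- attr(ir, "snp_ids")
  tot <- numeric(k)
  keep <- !ir$flagged
  t1 <- tapply(ir$neglogp[keep], factor(ir$i[keep], levels = seq_len(k)), sum)
  t2 <- tapply(ir$neglogp[keep], factor(ir$j[keep], levels = seq_len(k)), sum)
  tot <- ifelse(is.na(t1), 0, t1) + ifelse(is.na(t2), 0, t2)
  stats::setNames(as.numeric(tot), ids)
}

# Dense symmetric similarity matrix from pair-level -log10 p, rescaled
# to [0, 1] by the maximum; diagonal 0.
similarity_matrix <- function(ir) {
  k <- attr(ir, "n_snps")
  S <- matrix(0, k, k, dimnames = list(attr(ir, "snp_ids"), attr(ir, "snp_ids")))
  mx <- max(ir$neglogp)
  if (mx <= 0) stop_data("all interaction p-values are 1: empty similarity")
  v <- ir$neglogp / mx
  S[cbind(ir$i, ir$j)] <- v
  S[cbind(ir$j, ir$i)] <- v
  S
}

#' Choose the soft-thresholding power by scale-free fit
#'
#' For each candidate power, connectivity `k_i = sum_j s_ij^power` is
#' binned (10 equal-count bins) and the scale-free model fit R^2 of
#' `log10 freq ~ log10 k` is computed; the chosen power is the smallest
#' with R^2 >= `r2_min` and negative slope, falling back to
#' `fallback` when none qualifies.
#'
#' @param S similarity matrix in `[0, 1]`.
#' @param powers candidate powers (default 1:20).
#' @param r2_min target fit (default 0.8).
#' @param fallback power used when no candidate fits (default 6).
#' @return chosen power; attribute `"fit"` is the per-power table.
#' @export
pick_soft_power <- function(S, powers = 1:20, r2_min = 0.8, fallback = 6L) {
  fit <- data.frame(power = powers, r2 = NA_real_, slope = NA_real_)
  for (r in seq_along(powers)) {
    A <- S ^ powers[r]
    diag(A) <- 0
    k <- rowSums(A)
    k <- k[k > 0]
    if (length(unique(k)) < 3) next
    br <- seq(min(k), max(k), length.out = 11)   # equal-width bins
    bin <- cut(k, breaks = br, include.lowest = TRUE)
    freq <- tapply(k, bin, length) / length(k)
    kmid <- tapply(k, bin, mean)
    okb <- !is.na(freq) & freq > 0
    if (sum(okb) < 3) next
    lx <- log10(kmid[okb]); ly <- log10(freq[okb])
    if (stats::sd(lx) == 0 || stats::sd(ly) == 0) next
    fit$r2[r] <- stats::cor(lx, ly)^2
    fit$slope[r] <- stats::cov(lx, ly) / stats::var(lx)
  }
  ok <- which(!is.na(fit$r2) & fit$r2 >= r2_min & fit$slope < 0)
  power <- if (length(ok)) powers[min(ok)] else as.integer(fallback)
  structure(power, fit = fit)
}

#' Build the weighted interaction network
#'
#' Similarity `s_ij` is the pair `-log10 p` rescaled to `[0, 1]` by its
#' maximum; adjacency is `a_ij = s_ij^power`; the topological overlap is
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`.
#'
#' @param ir an `interaction_result`.
#' @param soft_power soft-thresholding power; `NULL` selects it by
#'   [pick_soft_power()].
#' @return list: `similarity`, `adjacency`, `tom`, `dissim`
#'   (= 1 - TOM), `soft_power`, `power_fit`.
#' @export
build_network <- function(ir, soft_power = NULL) {
  S <- similarity_matrix(ir)
  if (is.null(soft_power)) {
    soft_power <- pick_soft_power(S)
  } else if (soft_power < 1) stop_config("soft_power must be >= 1")
  A <- S ^ as.numeric(soft_power)
  diag(A) <- 0
  k <- rowSums(A)
  L <- A %*% A
  kmin <- outer(k, k, pmin)
  TOM <- (L + A) / (kmin + 1 - A)
  diag(TOM) <- 1
  list(similarity = S, adjacency = A, tom = TOM, dissim = 1 - TOM,
       soft_power = as.integer(soft_power),
       power_fit = attr(soft_power, "fit"))
}

# WGCNA-style module color sequence (size rank order; largest =
# turquoise, unassigned = grey).
module_colors <- function(n) {
  cols <- c("turquoise", "blue", "brown", "yellow", "green", "red",
            "black", "pink", "magenta", "purple", "greenyellow", "tan",
            "salmon", "cyan", "midnightblue", "lightcyan", "grey60",
            "lightgreen", "lightyellow", "royalblue", "darkred",
            "darkgreen", "darkturquoise", "darkgrey", "orange",
            "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
            "paleturquoise", "violet", "darkolivegreen", "darkmagenta")
  if (n <= length(cols)) cols[seq_len(n)] else
    c(cols, paste0("module", seq_len(n - length(cols))))
}

#' Detect modules from the TOM dissimilarity
#'
#' Average-linkage hierarchical clustering followed by a dynamic-style
#' tree cut: branches are taken from a static cut at
#' `cut_height_frac * max(merge height)` and accepted as modules only
#' when they (i) hold at least `min_module_size` SNPs and (ii) have a
#' core scatter - the mean dissimilarity among the most tightly
#' connected `min_module_size` members - below `max_core_scatter`,
#' scaled between the 5th percentile of dissimilarity and the cut
#' height. The scatter criterion is what sends clusters of
#' unstructured similarity to `"grey"`: a random branch is no tighter
#' at its core than the dissimilarity bulk, while a genuine module's
#' core sits far below it. Accepted modules are named by size rank
#' along the WGCNA color sequence (largest = `"turquoise"`).
#'
#' @param dissim TOM dissimilarity matrix.
#' @param min_module_size minimum module size (default 30).
#' @param cut_height_frac static cut as a fraction of the tallest merge
#'   (default 0.99).
#' @param max_core_scatter acceptance criterion on the scaled core
#'   scatter (default 0.82, the mid "deep split" convention).
#' @return named character vector of module labels (one per SNP);
#'   attribute `"dendrogram"` is the `hclust` object.
#' @export
detect_modules <- function(dissim, min_module_size = 30L,
                           cut_height_frac = 0.99,
                           max_core_scatter = 0.82) {
  k <- nrow(dissim)
  if (k < min_module_size) stop_data("fewer SNPs than min_module_size")
  hc <- stats::hclust(stats::as.dist(dissim), method = "average")
  cut_h <- cut_height_frac * max(hc$height)
  cl <- stats::cutree(hc, h = cut_h)
  base <- stats::quantile(dissim[upper.tri(dissim)], 0.05, names = FALSE)
  span <- max(cut_h - base, 1e-12)
  sizes <- table(cl)
  accepted <- integer(0)
  for (c in as.integer(names(sizes))) {
    if (sizes[[as.character(c)]] < min_module_size) next
    idx <- which(cl == c)
    dsub <- dissim[idx, idx, drop = FALSE]
    conn <- rowSums(dsub)
    core <- idx[order(conn)][seq_len(min(min_module_size, length(idx)))]
    dcore <- dissim[core, core]
    core_scatter <- mean(dcore[upper.tri(dcore)])
    scatter_scaled <- (core_scatter - base) / span
    if (scatter_scaled <= max_core_scatter)
      accepted <- c(accepted, c)
  }
  labels <- rep("grey", k)
  if (length(accepted)) {
    ord <- accepted[order(-sizes[as.character(accepted)])]
    cols <- module_colors(length(ord))
    for (r in seq_along(ord)) labels[cl == ord[r]] <- cols[r]
  }
  names(labels) <- rownames(dissim)
  attr(labels, "dendrogram") <- hc
  labels
}

#' Module eigengenes
#'
#' First principal component across samples of the standardized dosage
#' matrix of each module's SNPs, returned unit-norm with the sign fixed
#' so the eigengene correlates positively with the module's mean
#' standardized dosage. Single-SNP modules return that standardized
#' dosage (unit-normalized). The `"grey"` label is skipped.
#'
#' @param G a [genotype_matrix()] of the scanned SNP panel.
#' @param labels module labels from [detect_modules()] (aligned to the
#'   columns of `G`).
#' @return samples x modules matrix of eigengenes; attribute
#'   `"var_explained"` gives the fraction of standardized variance
#'   captured per module.
#' @export
module_eigengene <- function(G, labels) {
  dos <- impute_mean(G$dosage)
  mods <- setdiff(unique(labels), "grey")
  if (!length(mods)) stop_data("no non-grey modules")
  ME <- matrix(NA_real_, nrow(dos), length(mods),
               dimnames = list(G$samples, mods))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    Xm <- scale(dos[, labels == m, drop = FALSE])
    Xm[, !is.finite(colSums(Xm))] <- 0        # constant SNPs
    sv <- svd(Xm, nu = 1, nv = 0)
    u <- sv$u[, 1]
    mean_dos <- rowMeans(Xm)
    if (stats::sd(mean_dos) > 0 && stats::cor(u, mean_dos) < 0) u <- -u
    ME[, m] <- u
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  attr(ME, "var_explained") <- ve
  ME
}

#' Module-eigengene association with the trait
#'
#' Wald test for each eigengene as a fixed effect in the GLMM with
#' age + sex covariates and kinship `K` (see [glmm_wald()]).
#'
#' @param ME eigengene matrix from [module_eigengene()].
#' @param y INT-transformed trait.
#' @param covariates data.frame with `age`, `sex`.
#' @param K kinship/GRM.
#' @param labels optional module labels (adds module sizes to the
#'   output).
#' @return data.frame (`module`, `n_snps`, `coef`, `se`, `z`, `p`)
#'   sorted by p.
#' @export
module_association <- function(ME, y, covariates, K, labels = NULL) {
  X <- cbind(`(Intercept)` = 1, age = covariates$age, sex = covariates$sex)
  res <- lapply(colnames(ME), function(m) {
    w <- glmm_wald(y, X, ME[, m], K)
    data.frame(module = m,
               n_snps = if (is.null(labels)) NA_integer_ else sum(labels == m),
               coef = w$coef, se = w$se, z = w$z, p = w$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$p), , drop = FALSE]
}
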