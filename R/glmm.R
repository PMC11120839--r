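# Empirical GRM and GLMM score-test association.
#
# The null model is y = X beta + g + e with g ~ N(0, sigma_g2 * K).
# Variance components are estimated by REML, profiling the likelihood
# over h2 = sigma_g2 / (sigma_g2 + sigma_e2) on the eigenbasis of K:
# one O(n^3) eigendecomposition, then O(n) per candidate h2 evaluated by
# 1-D bounded search. Per-SNP association uses the score statistic
# U = g' P y with variance g' P g, requiring no per-SNP refit.

#' Empirical genetic relationship matrix
#'
#' Centered GRM `K = W W' / m`, where column j of `W` is the dosage
#' centered by twice the sample allele frequency. Missing dosages are
#' mean-imputed (which centers them to exactly zero).
#'
#' @param G a [genotype_matrix()] or dosage matrix (samples x SNPs).
#' @return symmetric n x n matrix with sample-id dimnames.
#' @export
compute_grm <- function(G) {
  ids <- NULL
  if (inherits(G, "genotype_matrix")) { ids <- G$samples; G <- G$dosage }
  if (ncol(G) < 2) stop_data("need at least 2 SNPs to compute a GRM")
  W <- impute_mean(G)
  W <- sweep(W, 2L, colMeans(W))
  K <- tcrossprod(W) / ncol(W)
  if (!is.null(ids)) dimnames(K) <- list(ids, ids)
  K
}

#' Fit the GLMM null model by REML
#'
#' @param y numeric trait (already INT-transformed in the standard
#'   pipeline); missing values are not allowed (complete cases only).
#' @param X fixed-effect design matrix (with intercept column);
#'   a data.frame of covariates is accepted and an intercept prepended.
#' @param K positive semi-definite kinship/GRM aligned to `y`.
#' @return A `glmm_null` object: fixed-effect estimates `beta`,
#'   variance components `sigma_g2`/`sigma_e2`, heritability `h2`,
#'   projection matrix `P` (with `P X = 0`), `Py = P y`, the REML
#'   log-likelihood, and the eigendecomposition reused by refits.
#' @export
fit_null <- function(y, X, K) {
  if (is.data.frame(X)) X <- cbind(`(Intercept)` = 1, as.matrix(X))
  X <- as.matrix(X)
  n <- length(y)
  if (anyNA(y) || anyNA(X)) stop_data("missing values in y or X: use complete cases")
  if (nrow(X) != n || nrow(K) != n) stop_data("y, X, K dimensions disagree")
  if (qr(X)$rank < ncol(X)) stop_data("collinear covariates in the design")
  p <- ncol(X)
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)

  reml <- function(h2) {
    v <- h2 * d + (1 - h2)
    w <- 1 / v
    XtWX <- crossprod(Xs, Xs * w)
    XtWy <- crossprod(Xs, ys * w)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
    r <- ys - Xs %*% beta
    rss <- sum(w * r^2)
    s2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(s2) + sum(log(v)) +
                    2 * sum(log(diag(ch))) + (n - p))
    list(ll = ll, beta = drop(beta), s2 = s2)
  }
  opt <- stats::optimize(function(h) reml(h)$ll, c(0, 1 - 1e-6),
                         maximum = TRUE, tol = 1e-8)
  h2 <- opt$maximum
  at0 <- reml(0)
  if (at0$ll >= opt$objective) h2 <- 0
  fit <- reml(h2)
  s2 <- fit$s2
  sigma_g2 <- h2 * s2
  sigma_e2 <- (1 - h2) * s2
  vinv_diag <- 1 / (sigma_g2 * d + sigma_e2)
  Vinv <- U %*% (vinv_diag * t(U))
  VinvX <- Vinv %*% X
  XtVX <- crossprod(X, VinvX)
  XtVXi <- solve(XtVX)
  P <- Vinv - VinvX %*% XtVXi %*% t(VinvX)
  beta <- drop(fit$beta)
  names(beta) <- colnames(X)
  structure(list(beta = beta, beta_cov = XtVXi,
                 sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, h2 = h2,
                 P = P, Py = drop(P %*% y),
                 loglik = if (h2 == 0) at0$ll else opt$objective,
                 y = y, X = X, eigen_d = d, n = n),
            class = "glmm_null")
}

#' @export
print.glmm_null <- function(x, ...) {
  cat(sprintf("GLMM null model: n = %d, h2 = %.3f (sigma_g2 = %.4f, sigma_e2 = %.4f)\n",
              x$n, x$h2, x$sigma_g2, x$sigma_e2))
  print(round(x$beta, 4))
  invisible(x)
}

#' Score test for a single variant
#'
#' `U = g' P y`, `var = g' P g`, `p = P(chi2_1 >= U^2/var)`. A positive
#' score means the minor allele increases the (transformed) trait.
#' Variants constant after projection are flagged and given p = 1.
#'
#' @param null a fitted [fit_null()] object.
#' @param g dosage vector (missing values mean-imputed).
#' @return list `(score, score_var, p, flagged)`.
#' @export
score_test <- function(null, g) {
  if (anyNA(g)) { mu <- mean(g, na.rm = TRUE); g[is.na(g)] <- mu }
  U <- sum(g * null$Py)
  v <- drop(crossprod(g, null$P %*% g))
  if (v <= 1e-10) {
    warning("variant constant after projection; p set to 1")
    return(list(score = 0, score_var = v, p = 1, flagged = TRUE))
  }
  list(score = U, score_var = v,
       p = stats::pchisq(U^2 / v, 1, lower.tail = FALSE), flagged = FALSE)
}

#' Genome-wide score-test scan
#'
#' Vectorized [score_test()] over every SNP of a genotype matrix.
#'
#' @param null a fitted [fit_null()] object.
#' @param G a [genotype_matrix()] (samples must match the null fit).
#' @return data.frame (`snp_id`, `chr`, `pos`, `maf`, `score`,
#'   `score_var`, `p`, `flagged`) of class `gwas_result`.
#' @export
score_scan <- function(null, G) {
  dos <- impute_mean(G$dosage)
  if (nrow(dos) != null$n) stop_data("genotypes do not match the null model samples")
  U <- drop(crossprod(dos, null$Py))
  v <- colSums(dos * (null$P %*% dos))
  flagged <- v <= 1e-10
  p <- rep(1, length(U))
  p[!flagged] <- stats::pchisq(U[!flagged]^2 / v[!flagged], 1,
                               lower.tail = FALSE)
  out <- data.frame(snp_id = G$snps$snp_id, chr = G$snps$chr,
                    pos = G$snps$pos, maf = pmin(G$snps$maf, 1 - G$snps$maf),
                    score = U, score_var = v, p = p, flagged = flagged,
                    stringsAsFactors = FALSE)
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Run the full GWAS stage
#'
#' INT-transforms the phenotype, fits the GLMM null model with age and
#' sex covariates and the given kinship, and scans all SNPs.
#'
#' @param G a [genotype_matrix()].
#' @param phenotype data.frame (`iid`, `pheno`, `age`, `sex`) aligned to
#'   `G$samples` by `iid`.
#' @param K kinship/GRM; defaults to [compute_grm()] of `G`.
#' @return list: `gwas` (a `gwas_result`), `null` (the fitted null
#'   model), `y_int` (transformed trait), `K`.
#' @export
run_gwas <- function(G, phenotype, K = NULL) {
  ph <- phenotype[match(G$samples, phenotype$iid), ]
  if (anyNA(ph$iid)) stop_data("phenotype table missing some genotyped samples")
  if (is.null(K)) K <- compute_grm(G)
  y <- int_transform(ph$pheno)
  X <- cbind(`(Intercept)` = 1, age = ph$age, sex = ph$sex)
  null <- fit_null(y, X, K)
  list(gwas = score_scan(null, G), null = null, y_int = y, K = K,
       covariates = ph[, c("age", "sex")])
}

#' Classify GWAS significance
#'
#' Strict thresholds: genome-wide when p < `gw`, suggestive when
#' `gw <= p < suggestive`.
#'
#' @param p p-values (or a `gwas_result`).
#' @param gw genome-wide threshold (default 5e-8).
#' @param suggestive suggestive threshold (default 1e-5).
#' @return factor with levels `genome-wide`, `suggestive`, `none`.
#' @export
classify_significance <- function(p, gw = 5e-8, suggestive = 1e-5) {
  if (is.data.frame(p)) p <- p$p
  lab <- ifelse(p < gw, "genome-wide", ifelse(p < suggestive, "suggestive", "none"))
  factor(lab, levels = c("genome-wide", "suggestive", "none"))
}

#' Genomic-control inflation factor
#'
#' `lambda = median(chi2) / 0.4549...`, the null median of a 1-df
#' chi-square.
#'
#' @param p p-values (or a `gwas_result`).
#' @return scalar lambda.
#' @export
genomic_inflation <- function(p) {
  if (is.data.frame(p)) p <- p$p
  if (length(p) < 100) stop_data("need >= 100 SNPs for a stable lambda")
  chi <- stats::qchisq(p, 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, 1, lower.tail = FALSE)
}

#' Wald test for an extra fixed effect in the GLMM
#'
#' Refits the REML model with `z` appended to the fixed-effect design
#' and reports its coefficient, Wald z statistic and two-sided normal
#' p-value. Used for module-eigengene association.
#'
#' @param y trait vector; @param X covariate design (with intercept);
#' @param z the additional predictor; @param K kinship.
#' @return list `(coef, se, z, p, h2)`.
#' @export
glmm_wald <- function(y, X, z, K) {
  if (is.data.frame(X)) X <- cbind(`(Intercept)` = 1, as.matrix(X))
  Xz <- cbind(X, z = z)
  if (qr(Xz)$rank < ncol(Xz))
    stop_data("predictor is collinear with the covariates")
  fit <- fit_null(y, Xz, K)
  k <- ncol(Xz)
  coef <- fit$beta[k]
  se <- sqrt(fit$beta_cov[k, k])
  zstat <- coef / se
  list(coef = unname(coef), se = se, z = unname(zstat),
       p = 2 * stats::pnorm(-abs(zstat)), h2 = fit$h2)
}
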