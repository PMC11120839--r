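# Rank-based replication: does a module's SNP set sit unusually high in
# the replication GWAS statistic ranking?

#' Rank-based gene-set (SNP-set) test
#'
#' Wilcoxon rank-sum test of whether the statistics indexed by `index`
#' are highly ranked among `statistics`. Alternatives:
#' \describe{
#'   \item{mixed}{one-sided on absolute statistics (set larger),
#'     regardless of effect direction - the default for SNP modules.}
#'   \item{up / down}{one-sided on signed statistics.}
#'   \item{either}{two-sided on signed statistics.}
#' }
#' Uses the exact rank-sum distribution when the set has at most
#' `exact_max` members and there are no ties, otherwise the normal
#' approximation with continuity and tie correction.
#'
#' @param index integer or logical index of the set within `statistics`.
#' @param statistics numeric vector of per-SNP statistics (e.g., signed
#'   GWAS scores).
#' @param alternative one of `"mixed"`, `"up"`, `"down"`, `"either"`.
#' @param exact_max largest set size for exact enumeration (default 10).
#' @return p-value in (0, 1].
#' @export
gene_set_test <- function(index, statistics,
                          alternative = c("mixed", "up", "down", "either"),
                          exact_max = 10L) {
  alternative <- match.arg(alternative)
  if (is.logical(index)) index <- which(index)
  n <- length(statistics)
  n1 <- length(index)
  if (n1 == 0) stop_data("empty set")
  if (n1 >= n) stop_data("set must be a strict subset of the statistics")
  x <- if (alternative == "mixed") abs(statistics) else statistics
  r <- rank(x)
  w <- sum(r[index]) - n1 * (n1 + 1) / 2      # Mann-Whitney U of the set
  n2 <- n - n1
  ties <- any(duplicated(x))
  side <- switch(alternative, mixed = "greater", up = "greater",
                 down = "less", either = "two.sided")
  if (n1 <= exact_max && !ties) {
    p_ge <- stats::pwilcox(w - 1, n1, n2, lower.tail = FALSE)  # P(W >= w)
    p_le <- stats::pwilcox(w, n1, n2)
    p <- switch(side, greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(x)
    sigma2 <- n1 * n2 / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    sigma <- sqrt(sigma2)
    z_ge <- (w - mu - 0.5) / sigma
    z_le <- (w - mu + 0.5) / sigma
    p_ge <- stats::pnorm(z_ge, lower.tail = FALSE)
    p_le <- stats::pnorm(z_le)
    p <- switch(side, greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
  }
  max(p, .Machine$double.xmin)
}

#' Replicate discovery modules in an independent cohort
#'
#' For each discovery module, its SNPs are matched by identifier into
#' the replication GWAS and tested with [gene_set_test()] against all
#' replication statistics. A module with under `min_overlap` of its
#' SNPs present in the replication panel is marked untestable.
#'
#' @param labels module labels (named by snp id) from
#'   [detect_modules()].
#' @param rep_gwas `gwas_result` of the replication cohort.
#' @param threshold replication significance threshold (default 0.01,
#'   strict `<`).
#' @param alternative passed to [gene_set_test()] (default `"mixed"`).
#' @param min_overlap minimum fraction of module SNPs that must match
#'   (default 0.5).
#' @return data.frame (`module`, `n_set`, `n_matched`, `alternative`,
#'   `p`, `replicated`, `testable`), one row per non-grey module.
#' @export
replicate_modules <- function(labels, rep_gwas, threshold = 0.01,
                              alternative = "mixed", min_overlap = 0.5) {
  mods <- setdiff(unique(labels), "grey")
  if (!length(mods)) stop_data("no modules to replicate")
  stat <- rep_gwas$score / sqrt(pmax(rep_gwas$score_var, 1e-300))
  names(stat) <- rep_gwas$snp_id
  res <- lapply(mods, function(m) {
    ids <- names(labels)[labels == m]
    hit <- ids[ids %in% names(stat)]
    testable <- length(hit) >= min_overlap * length(ids) && length(hit) > 0 &&
      length(hit) < length(stat)
    if (length(hit) < length(ids))
      message(sprintf("module %s: %d of %d SNPs absent from replication panel",
                      m, length(ids) - length(hit), length(ids)))
    p <- if (testable)
      gene_set_test(match(hit, names(stat)), unname(stat), alternative)
    else NA_real_
    data.frame(module = m, n_set = length(ids), n_matched = length(hit),
               alternative = alternative, p = p,
               replicated = isTRUE(p < threshold), testable = testable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$p), , drop = FALSE]
}
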