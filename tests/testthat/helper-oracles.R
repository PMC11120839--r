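# Independent oracles kept separate from the implementations they check.

# Exact HWE enumeration: conditional probability of every heterozygote
# configuration given the allele counts, from the closed multinomial /
# hypergeometric expression evaluated in log space; two-sided p as the
# total mass of configurations no more probable than the observed one.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_aa + n_Aa
  nA <- 2 * n - na
  hets <- seq(min(na, nA) %% 2, min(na, nA), by = 2)
  logp <- sapply(hets, function(h) {
    hom_a <- (na - h) / 2
    hom_A <- (nA - h) / 2
    lfactorial(n) - lfactorial(hom_A) - lfactorial(h) - lfactorial(hom_a) +
      h * log(2) + lfactorial(na) + lfactorial(nA) - lfactorial(2 * n)
  })
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  sum(p[p <= p[match(n_Aa, hets)] * (1 + 1e-10)])
}

# The greedy LD pruning rule re-applied literally (left-to-right, tag =
# leftmost, extend while D' >= threshold and the block is not full).
ld_prune_oracle <- function(dos, dprime_min = 0.9, max_block = 1000) {
  tags <- integer(0)
  tag <- NA_integer_; size <- 0L
  for (s in seq_len(ncol(dos))) {
    linked <- FALSE
    if (!is.na(tag) && size < max_block)
      linked <- as.numeric(estimate_dprime(dos[, tag], dos[, s])) >= dprime_min
    if (linked) size <- size + 1L
    else { tag <- s; size <- 1L; tags <- c(tags, s) }
  }
  tags
}
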