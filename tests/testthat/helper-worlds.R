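# Shared simulation worlds and small constructors used across tests.

# Build an interaction_result directly from a similarity-like matrix of
# -log10 p values in [0, 1] * scale (for tests of the network stage that
# do not need a genotype scan).
make_ir <- function(S, scale = 6) {
  k <- nrow(S)
  ut <- which(upper.tri(S), arr.ind = TRUE)
  neglogp <- S[ut] * scale
  df <- data.frame(i = ut[, 1], j = ut[, 2],
                   snp_i = paste0("s", ut[, 1]), snp_j = paste0("s", ut[, 2]),
                   beta = 0, t = 0, p = 10^(-neglogp), neglogp = neglogp,
                   flagged = FALSE)
  attr(df, "n_snps") <- k
  attr(df, "snp_ids") <- paste0("s", seq_len(k))
  class(df) <- c("interaction_result", "data.frame")
  df
}

# Unrelated cohort (founder couples only): the regime in which the OLS
# pair scan is exactly valid; used for null-calibration checks.
founders_cohort <- function(seed, n = 700, n_snps = 150,
                            maf_range = c(0.05, 0.5)) {
  spec <- pedigree_spec(n_families = n / 2, generations = 1,
                        founder_maf_range = maf_range)
  simulate_pedigree_genotypes(spec, n_snps = n_snps, seed = seed)
}

# Hub-SNP world: a module of `msize` SNPs carrying both weak aligned
# main effects (what makes the module marginally visible and
# replicable) and dense pairwise interactions of random sign (what
# makes it cluster in the interaction network). SNPs unlinked.
hub_world <- function(seed, n_fam = 300, k = 60, msize = 12,
                      var_epi = 0.45, main_r2 = 0.012) {
  spec <- pedigree_spec(n_families = n_fam, generations = 2,
                        offspring_per_couple = 3)
  sim <- simulate_pedigree_genotypes(spec, n_snps = k, seed = seed)
  K <- expected_kinship(sim$pedigree)
  set.seed(seed + 777)
  planted <- sort(sample(k, msize))
  pick <- t(combn(planted, 2))
  signs <- sample(c(-1, 1), nrow(pick), TRUE)
  dos <- sim$genotypes$dosage
  comp <- rowSums(sapply(seq_len(nrow(pick)), function(r)
    signs[r] * dos[, pick[r, 1]] * dos[, pick[r, 2]]))
  base_var <- 1.15 + msize * main_r2 * 1.15
  beta <- sqrt(var_epi / (1 - var_epi) * base_var / stats::var(comp))
  pairs <- data.frame(i = pick[, 1], j = pick[, 2], beta = beta * signs)
  maf <- pmin(colMeans(dos) / 2, 1 - colMeans(dos) / 2)
  mains <- data.frame(snp = planted,
                      beta = sqrt(main_r2 * base_var /
                                    pmax(2 * maf[planted] * (1 - maf[planted]),
                                         0.05)))
  model <- trait_model(sigma_g2 = 0.4, sigma_e2 = 0.6,
                       planted_pairs = pairs, planted_mains = mains)
  ph <- simulate_phenotype(sim$genotypes, K, model, seed = seed + 321)
  list(sim = sim, K = K, ph = ph, planted = planted, model = model,
       spec = spec)
}

# LD-block world: the module is a contiguous block of mutually
# correlated SNPs (copy-with-flip founder haplotypes, co-transmitted),
# with aligned main effects and same-sign within-block interactions.
# This is the world in which a module eigengene is a meaningful summary
# (the first PC tracks the regional dosage).
ld_block_world <- function(seed, n_fam = 250, k = 40, msize = 10,
                           flip = 0.08) {
  spec <- pedigree_spec(n_families = n_fam, generations = 2,
                        offspring_per_couple = 2)
  sim <- simulate_pedigree_genotypes(spec, n_snps = k, seed = seed,
                                     n_chr = 4,
                                     ld = list(flip_prob = flip,
                                               block_size = msize))
  K <- expected_kinship(sim$pedigree)
  planted <- seq_len(msize)   # first block
  pick <- t(combn(planted, 2))
  dos <- sim$genotypes$dosage
  comp <- rowSums(sapply(seq_len(nrow(pick)), function(r)
    dos[, pick[r, 1]] * dos[, pick[r, 2]]))
  beta <- sqrt(0.3 / 0.7 * 1.15 / stats::var(comp))
  maf <- pmin(colMeans(dos) / 2, 1 - colMeans(dos) / 2)
  mains <- data.frame(snp = planted,
                      beta = sqrt(0.01 * 1.15 /
                                    pmax(2 * maf[planted] * (1 - maf[planted]),
                                         0.05)))
  model <- trait_model(sigma_g2 = 0.4, sigma_e2 = 0.6,
                       planted_mains = mains,
                       planted_pairs = data.frame(i = pick[, 1],
                                                  j = pick[, 2],
                                                  beta = beta))
  ph <- simulate_phenotype(sim$genotypes, K, model, seed = seed + 100)
  list(sim = sim, K = K, ph = ph, planted = planted, model = model,
       spec = spec, flip = flip, msize = msize)
}

# The module-recovery world at the scale and signal level stated for
# the headline recovery check: 2000 candidate SNPs, a planted 30-SNP
# module whose pairwise effects (degree-4 random graph, random signs)
# together contribute ~5% of trait variance.
recovery_world <- function(seed, n_snps = 2000, msize = 30, degree = 4,
                           var_epi = 0.05) {
  spec <- pedigree_spec(n_families = 200, generations = 2,
                        offspring_per_couple = 3)
  sim <- simulate_pedigree_genotypes(spec, n_snps = n_snps, seed = seed)
  K <- expected_kinship(sim$pedigree)
  set.seed(seed + 777)
  planted <- sort(sample(n_snps, msize))
  allp <- t(combn(planted, 2))
  pick <- allp[sample(nrow(allp), msize * degree / 2), , drop = FALSE]
  signs <- sample(c(-1, 1), nrow(pick), TRUE)
  dos <- sim$genotypes$dosage
  comp <- rowSums(sapply(seq_len(nrow(pick)), function(r)
    signs[r] * dos[, pick[r, 1]] * dos[, pick[r, 2]]))
  beta <- sqrt(var_epi / (1 - var_epi) * 1.15 / stats::var(comp))
  pairs <- data.frame(i = pick[, 1], j = pick[, 2], beta = beta * signs)
  model <- trait_model(sigma_g2 = 0.4, sigma_e2 = 0.6,
                       planted_pairs = pairs)
  ph <- simulate_phenotype(sim$genotypes, K, model, seed = seed + 321)
  list(sim = sim, K = K, ph = ph, planted = planted, model = model,
       spec = spec)
}

# Run discovery (gwas -> prune -> scan -> network -> modules) on a
# world; returns everything needed to score recovery.
run_discovery <- function(w, soft_power = NULL, min_module_size = 10,
                          prune = FALSE) {
  gw <- run_gwas(w$sim$genotypes, w$ph, K = w$K)
  G <- w$sim$genotypes
  if (prune) {
    tags <- ld_prune(G)
    G <- epinet:::subset_snps(G, tags)
  }
  yadj <- residualize(gw$y_int, gw$covariates)
  ir <- pairwise_scan(G, yadj)
  net <- build_network(ir, soft_power = soft_power)
  lab <- detect_modules(net$dissim, min_module_size = min_module_size)
  list(gw = gw, G = G, ir = ir, net = net, lab = lab)
}

# Top (largest non-grey) module of a label vector, NA if none.
top_module <- function(lab) {
  tab <- table(lab[lab != "grey"])
  if (!length(tab)) return(NA_character_)
  names(sort(tab, decreasing = TRUE))[1]
}
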