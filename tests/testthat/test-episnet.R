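# Interaction scan, LD pruning, network construction, module detection,
# eigengenes and module-trait association.

test_that("GWAS p-value filter selects strictly and errors when empty", {
  gw <- data.frame(snp_id = paste0("s", 1:5), p = c(0.5, 0.009, 0.02, 1e-4, 0.01))
  expect_equal(filter_by_gwas(gw, 0.01), c(2L, 4L))
  expect_error(filter_by_gwas(data.frame(p = rep(0.5, 4))),
               class = "epinet_data_error")
})

test_that("D' estimation matches phased truth and direct likelihood maximization", {
  # no double heterozygotes: haplotypes are unambiguous, EM must equal
  # direct counting
  g1 <- c(rep(2, 10), rep(0, 30), rep(1, 10), rep(0, 10))
  g2 <- c(rep(2, 10), rep(0, 30), rep(0, 10), rep(1, 10))
  dp <- estimate_dprime(g1, g2)
  n <- length(g1)
  # direct count: AB haplotypes only from the (2,2) block etc.
  nAB <- 2 * 10; nAb <- 10; naB <- 10; nab <- 2 * 30 + 10 + 10
  expect_equal(unname(attr(dp, "haplotype_freqs")),
               c(nAB, nAb, naB, nab) / (2 * n), tolerance = 1e-8)
  # with double heterozygotes: EM equals the 1-D maximum likelihood
  set.seed(17)
  hA <- rbinom(600, 1, 0.4); hB <- ifelse(runif(600) < 0.7, hA, rbinom(600, 1, 0.4))
  h2A <- rbinom(600, 1, 0.4); h2B <- ifelse(runif(600) < 0.7, h2A, rbinom(600, 1, 0.4))
  G1 <- hA + h2A; G2 <- hB + h2B
  em <- estimate_dprime(G1, G2)
  pA <- mean(G1) / 2; pB <- mean(G2) / 2
  tab <- table(factor(G1, 0:2), factor(G2, 0:2))
  loglik <- function(pAB) {
    pAb <- pA - pAB; paB <- pB - pAB; pab <- 1 - pAB - pAb - paB
    if (min(pAb, paB, pab) < 0) return(-Inf)
    probs <- matrix(0, 3, 3)
    probs[1, 1] <- pab^2;        probs[1, 2] <- 2 * pab * paB
    probs[1, 3] <- paB^2;        probs[2, 1] <- 2 * pab * pAb
    probs[2, 2] <- 2 * (pAB * pab + pAb * paB)
    probs[2, 3] <- 2 * pAB * paB; probs[3, 1] <- pAb^2
    probs[3, 2] <- 2 * pAB * pAb; probs[3, 3] <- pAB^2
    sum(tab * log(pmax(probs, 1e-300)))
  }
  opt <- optimize(loglik, c(max(0, pA + pB - 1), min(pA, pB)), maximum = TRUE,
                  tol = 1e-10)
  expect_equal(unname(attr(em, "haplotype_freqs")["AB"]), opt$maximum,
               tolerance = 1e-5)
  # identical SNPs -> D' = 1; independent SNPs -> D' near 0
  expect_equal(as.numeric(estimate_dprime(G1, G1)), 1)
  set.seed(18)
  a <- rbinom(2000, 2, 0.3); b <- rbinom(2000, 2, 0.4)
  expect_lt(as.numeric(estimate_dprime(a, b)), 0.1)
  expect_error(estimate_dprime(a, rep(1, 2000)), class = "epinet_data_error")
})

test_that("LD pruning follows the greedy tag rule exactly", {
  set.seed(19)
  # 20 SNPs on one chromosome; SNPs 6-10 are copies of SNP 6 (perfect LD)
  dos <- sapply(1:20, function(j) rbinom(400, 2, 0.35))
  for (j in 7:10) dos[, j] <- dos[, 6]
  snps <- data.frame(snp_id = paste0("s", 1:20), chr = 1, pos = 1:20 * 1000,
                     allele_minor = "A", allele_major = "G")
  G <- genotype_matrix(dos, snps)
  tags <- ld_prune(G, dprime_min = 0.9, max_block = 1000)
  # independent oracle: re-apply the stated greedy rule directly
  oracle <- integer(0); tag <- NA
  for (s in 1:20) {
    linked <- !is.na(tag) &&
      as.numeric(estimate_dprime(dos[, tag], dos[, s])) >= 0.9
    if (!linked) { tag <- s; oracle <- c(oracle, s) }
  }
  expect_equal(as.integer(tags), oracle)
  expect_true(all(7:10 %in% setdiff(1:20, tags)))
  # idempotence
  Gp <- epinet:::subset_snps(G, tags)
  expect_equal(as.integer(ld_prune(Gp)), seq_along(tags))
  # block size cap: identical SNPs but max_block 2 -> a new tag every 2
  dos2 <- dos[, c(6, 6, 6, 6)] + 0
  G2 <- genotype_matrix(dos2, snps[1:4, ])
  expect_equal(as.integer(ld_prune(G2, max_block = 2)), c(1L, 3L))
})

test_that("pairwise scan matches lm, counts pairs, and flags degenerate pairs", {
  set.seed(23)
  n <- 300; k <- 12
  dos <- sapply(1:k, function(j) rbinom(n, 2, 0.3))
  dos[, 5] <- 1                                 # constant SNP
  snps <- data.frame(snp_id = paste0("s", 1:k), chr = 1, pos = 1:k,
                     allele_minor = "A", allele_major = "G")
  G <- genotype_matrix(dos, snps)
  y <- rnorm(n)
  ir <- pairwise_scan(G, y)
  expect_equal(nrow(ir), k * (k - 1) / 2)
  expect_true(all(ir$flagged[ir$i == 5 | ir$j == 5]))
  expect_true(all(ir$p[ir$flagged] == 1))
  for (q in c(1, 20, 40)) {
    if (ir$flagged[q]) next
    f <- summary(lm(y ~ dos[, ir$i[q]] * dos[, ir$j[q]]))
    expect_equal(ir$p[q], coef(f)[4, 4], tolerance = 1e-9)
    expect_equal(ir$beta[q], coef(f)[4, 1], tolerance = 1e-9)
  }
  expect_error(pairwise_scan(G, y[1:10]), class = "epinet_data_error")
})

test_that("pairwise scan recovers a planted interaction coefficient", {
  set.seed(29)
  n <- 2000
  g1 <- rbinom(n, 2, 0.3); g2 <- rbinom(n, 2, 0.4)
  y <- 0.2 * g1 - 0.1 * g2 + 1 * g1 * g2 + rnorm(n, sd = 0.5)
  snps <- data.frame(snp_id = c("a", "b"), chr = 1, pos = 1:2,
                     allele_minor = "A", allele_major = "G")
  ir <- pairwise_scan(genotype_matrix(cbind(g1, g2), snps), y)
  expect_lt(abs(ir$beta[1] - 1), 0.1)
})

test_that("interaction p-values are uniform under a permuted phenotype", {
  # common variants: with sparse product columns (low maf) the t
  # reference distribution is a poor finite-sample approximation and
  # the pair p-values become lumpy (documented limitation)
  sim <- founders_cohort(seed = 41, n = 700, n_snps = 150,
                         maf_range = c(0.2, 0.5))
  set.seed(42)
  yp <- sample(rnorm(nrow(sim$pedigree)))
  ir <- pairwise_scan(sim$genotypes, yp)
  expect_gte(nrow(ir), 1e4)
  expect_gt(ks.test(ir$p[!ir$flagged], "punif")$p.value, 0.01)
})

test_that("hotspot matrix aggregates and rescales per chromosome pair", {
  snps <- data.frame(snp_id = paste0("s", 1:6), chr = c(1, 1, 2, 2, 3, 3),
                     pos = 1:6)
  ir <- make_ir(matrix(0.5, 6, 6))
  # planted enrichment between chr 1 and 2
  sel <- (snps$chr[ir$i] == 1 & snps$chr[ir$j] == 2)
  ir$neglogp[sel] <- 5
  H <- interaction_hotspots(ir, snps, n_chr = 3)
  expect_equal(H[1, 2], 1)
  expect_equal(max(H, na.rm = TRUE), 1)
  expect_equal(H[1, 2], H[2, 1])
  expect_true(all(H[!is.na(H)] >= 0 & H[!is.na(H)] <= 1))
  # single populated cell -> 1 after rescaling; all-equal -> all 1
  ir2 <- make_ir(matrix(0.5, 6, 6))
  H2 <- interaction_hotspots(ir2, snps, n_chr = 3)
  expect_true(all(H2[!is.na(H2)] == 1))
})

test_that("per-SNP interaction totals obey the double-counting identity", {
  set.seed(31)
  S <- matrix(runif(64), 8, 8); S <- (S + t(S)) / 2; diag(S) <- 0
  ir <- make_ir(S)
  tot <- sum_effect_sizes(ir)
  expect_equal(sum(tot), 2 * sum(ir$neglogp))
  # a hub SNP with strong interactions ranks first
  S[1, ] <- S[, 1] <- 0.95; diag(S) <- 0
  expect_equal(which.max(sum_effect_sizes(make_ir(S))), c(s1 = 1L))
  # SNP in no estimable pair totals zero
  ir$flagged[ir$i == 2 | ir$j == 2] <- TRUE
  expect_equal(unname(sum_effect_sizes(ir)[2]), 0)
})

test_that("adjacency and TOM have the stated structure", {
  # two SNPs connected only to each other with similarity 1 -> TOM 1
  S <- matrix(0, 4, 4); S[1, 2] <- S[2, 1] <- 1
  net <- build_network(make_ir(S, scale = 1), soft_power = 1)
  expect_equal(net$tom[1, 2], 1)
  # two SNPs sharing all strong partners -> TOM near 1
  S2 <- matrix(0, 10, 10)
  S2[1, 3:10] <- S2[2, 3:10] <- 0.95
  S2 <- pmax(S2, t(S2))
  net2 <- build_network(make_ir(S2, scale = 1), soft_power = 1)
  expect_gt(net2$tom[1, 2], 0.85)
  # symmetry and unit bounds
  set.seed(33)
  S3 <- matrix(runif(100), 10, 10); S3 <- (S3 + t(S3)) / 2; diag(S3) <- 0
  net3 <- build_network(make_ir(S3), soft_power = 6)
  expect_equal(net3$adjacency, t(net3$adjacency))
  expect_equal(net3$tom, t(net3$tom), tolerance = 1e-12)
  expect_true(all(net3$tom >= 0 & net3$tom <= 1 + 1e-12))
  expect_error(build_network(make_ir(matrix(0, 5, 5))),
               class = "epinet_data_error")
  expect_error(build_network(make_ir(S3), soft_power = 0),
               class = "epinet_config_error")
})

test_that("soft power selection reports fits over 1..20 with fallback 6", {
  set.seed(34)
  S <- matrix(runif(400), 20, 20); S <- (S + t(S)) / 2; diag(S) <- 0
  sp <- pick_soft_power(S)
  fit <- attr(sp, "fit")
  expect_equal(fit$power, 1:20)
  chosen <- which(!is.na(fit$r2) & fit$r2 >= 0.8 & fit$slope < 0)
  if (length(chosen)) expect_equal(as.integer(sp), min(chosen))
  else expect_equal(as.integer(sp), 6L)
})

test_that("module detection separates planted blocks and rejects noise", {
  set.seed(35)
  k <- 160
  S <- matrix(runif(k * k, 0, 0.05), k, k)
  S[1:50, 1:50] <- runif(2500, 0.6, 1)
  S[51:95, 51:95] <- runif(45 * 45, 0.55, 0.95)
  S <- (S + t(S)) / 2; diag(S) <- 0
  lab <- detect_modules(build_network(make_ir(S), soft_power = 6)$dissim,
                        min_module_size = 30)
  nong <- setdiff(unique(lab), "grey")
  expect_length(nong, 2)
  expect_gte(mean(lab[1:50] == names(which.max(table(lab[1:50])))), 0.95)
  expect_gte(mean(lab[51:95] == names(which.max(table(lab[51:95])))), 0.95)
  expect_true(all(lab[96:160] == "grey"))
  expect_equal(unname(lab[1]), "turquoise")    # largest block first color
  # the largest module carries the first color of the sequence
  expect_equal(names(sort(table(lab[lab != "grey"]), decreasing = TRUE))[1],
               "turquoise")
  # null similarity (uniform random p-values, as the scan produces
  # under no signal) -> essentially everything grey
  for (sd0 in 1:3) {
    set.seed(sd0)
    S0 <- matrix(-log10(runif(k * k)), k, k)
    S0 <- (S0 + t(S0)) / 2; diag(S0) <- 0
    S0 <- S0 / max(S0)
    lab0 <- detect_modules(build_network(make_ir(S0), soft_power = 6)$dissim,
                           min_module_size = 30)
    expect_gt(mean(lab0 == "grey"), 0.9)
  }
  expect_error(detect_modules(matrix(0, 5, 5), min_module_size = 30),
               class = "epinet_data_error")
})

test_that("module eigengene is the leading PC with a fixed sign convention", {
  set.seed(37)
  n <- 200
  base <- rbinom(n, 2, 0.4)
  dos <- cbind(base, base, base, rbinom(n, 2, 0.3), rbinom(n, 2, 0.3))
  snps <- data.frame(snp_id = paste0("s", 1:5), chr = 1, pos = 1:5,
                     allele_minor = "A", allele_major = "G")
  G <- genotype_matrix(dos, snps)
  lab <- c(rep("turquoise", 3), rep("blue", 2))
  names(lab) <- snps$snp_id
  ME <- module_eigengene(G, lab)
  # identical columns -> ME proportional to the standardized column
  zc <- drop(scale(base)) / sqrt(sum(scale(base)^2))
  expect_equal(abs(cor(ME[, "turquoise"], zc)), 1, tolerance = 1e-10)
  expect_gt(cor(ME[, "turquoise"], base), 0)   # sign convention
  expect_equal(sum(ME[, "turquoise"]^2), 1)    # unit norm
  # variance explained matches a full SVD of the standardized matrix
  Xm <- scale(dos[, 1:3])
  sv <- svd(Xm)
  expect_equal(attr(ME, "var_explained")[["turquoise"]],
               sv$d[1]^2 / sum(sv$d^2), tolerance = 1e-10)
  # flipping minor/major orientation leaves the signed ME invariant
  G2 <- genotype_matrix(2 - dos, snps)
  ME2 <- module_eigengene(G2, lab)
  expect_equal(abs(cor(ME[, "blue"], ME2[, "blue"])), 1, tolerance = 1e-10)
  expect_gt(cor(ME2[, "turquoise"], 2 - base), 0)
})

test_that("module eigengene association detects a planted module and stays null otherwise", {
  for (s in 1:2) {
    w <- ld_block_world(s)
    y <- int_transform(w$ph$pheno)
    cov <- w$ph[, c("age", "sex")]
    k <- ncol(w$sim$genotypes$dosage)
    lab <- rep("grey", k)
    lab[w$planted] <- "turquoise"
    set.seed(s)
    lab[sample(setdiff(seq_len(k), w$planted), length(w$planted))] <- "blue"
    names(lab) <- w$sim$genotypes$snps$snp_id
    ME <- module_eigengene(w$sim$genotypes, lab)
    assoc <- module_association(ME, y, cov, w$K, lab)
    expect_lt(assoc$p[assoc$module == "turquoise"], 0.01)
    expect_gt(assoc$p[assoc$module == "blue"], 0.01)
    expect_equal(assoc$n_snps, rep(length(w$planted), 2))
  }
})

test_that("module association is calibrated under permutation of the eigengene", {
  w <- ld_block_world(3)
  y <- int_transform(w$ph$pheno)
  X <- cbind(1, age = w$ph$age, sex = w$ph$sex)
  lab <- rep("grey", 40); lab[w$planted] <- "turquoise"
  names(lab) <- w$sim$genotypes$snps$snp_id
  ME <- module_eigengene(w$sim$genotypes, lab)
  set.seed(99)
  pvals <- replicate(60, glmm_wald(y, X, sample(ME[, 1]), w$K)$p)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("the discovery chain recovers a hub module and replicates it", {
  caps <- reps <- numeric(3)
  for (s in 1:3) {
    w <- hub_world(s)
    d <- run_discovery(w, soft_power = 2, min_module_size = 10)
    top <- top_module(d$lab)
    expect_false(is.na(top))
    caps[s] <- mean(w$planted %in% which(d$lab == top))
    sim2 <- simulate_pedigree_genotypes(w$spec, ncol(w$sim$genotypes$dosage),
                                        seed = s + 4000)
    ph2 <- simulate_phenotype(sim2$genotypes,
                              expected_kinship(sim2$pedigree),
                              w$model, seed = s + 8000)
    gw2 <- run_gwas(sim2$genotypes, ph2)
    rp <- suppressMessages(replicate_modules(d$lab, gw2$gwas))
    reps[s] <- rp$p[rp$module == top]
  }
  expect_true(all(caps >= 0.8))
  expect_lt(median(reps), 0.01)
})
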