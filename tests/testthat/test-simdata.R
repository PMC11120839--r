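# Pedigree/genotype/phenotype simulator.

test_that("gene dropping obeys Mendelian certainty and determinism", {
  ped <- data.frame(fid = "f1",
                    iid = c("pa", "ma", paste0("c", 1:6)),
                    father = c(NA, NA, rep("pa", 6)),
                    mother = c(NA, NA, rep("ma", 6)),
                    sex = c(1L, 2L, rep(1L, 6)), generation = c(1, 1, rep(2, 6)))
  # father homozygous 1/1, mother 0/0 -> every child heterozygous
  fh1 <- matrix(1L, 2, 5, dimnames = list(c("pa", "ma"), NULL))
  fh2 <- matrix(1L, 2, 5, dimnames = list(c("pa", "ma"), NULL))
  fh1["ma", ] <- 0L; fh2["ma", ] <- 0L
  haps <- gene_drop(ped, fh1, fh2, seed = 1)
  dos <- haps$h1 + haps$h2
  expect_true(all(dos[paste0("c", 1:6), ] == 1))

  spec <- pedigree_spec(n_families = 5, generations = 3,
                        offspring_per_couple = 2)
  a <- simulate_pedigree_genotypes(spec, n_snps = 50, seed = 9)
  b <- simulate_pedigree_genotypes(spec, n_snps = 50, seed = 9)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$pedigree, b$pedigree)
})

test_that("founder allele frequency matches the binomial sampling oracle", {
  spec <- pedigree_spec(n_families = 200, generations = 1,
                        founder_maf_range = c(0.3, 0.3))
  sim <- simulate_pedigree_genotypes(spec, n_snps = 1, seed = 4)
  n_alleles <- 2 * nrow(sim$pedigree)          # 400 founders, 800 alleles
  phat <- mean(sim$genotypes$dosage[, 1]) / 2
  se <- sqrt(0.3 * 0.7 / n_alleles)
  expect_lt(abs(phat - 0.3), 3 * se)
})

test_that("allele frequency is conserved in expectation through generations", {
  spec <- pedigree_spec(n_families = 40, generations = 3,
                        offspring_per_couple = 2,
                        founder_maf_range = c(0.25, 0.25))
  freqs <- sapply(1:15, function(s) {
    sim <- simulate_pedigree_genotypes(spec, n_snps = 20, seed = 100 + s)
    last <- sim$pedigree$generation == max(sim$pedigree$generation)
    mean(sim$genotypes$dosage[last, ]) / 2
  })
  # mean over seeds and SNPs of the final-generation frequency
  expect_lt(abs(mean(freqs) - 0.25), 0.015)
})

test_that("expected_kinship reproduces textbook values and validates input", {
  # unrelated founders -> identity
  ped0 <- data.frame(iid = paste0("f", 1:4), father = NA_character_,
                     mother = NA_character_)
  expect_equal(unname(expected_kinship(ped0)), diag(4))
  # full sibs share 0.5 on the relationship scale
  ped <- data.frame(iid = c("pa", "ma", "s1", "s2"),
                    father = c(NA, NA, "pa", "pa"),
                    mother = c(NA, NA, "ma", "ma"))
  K <- expected_kinship(ped)
  expect_equal(K["s1", "s2"], 0.5)
  expect_equal(K["pa", "s1"], 0.5)
  expect_equal(unname(diag(K)), rep(1, 4))
  # individual as its own ancestor -> error
  bad <- data.frame(iid = c("a", "b"), father = c("b", "a"),
                    mother = c(NA, NA))
  expect_error(expected_kinship(bad), class = "epinet_pedigree_error")
})

test_that("expected_kinship matches a gene-dropping Monte-Carlo oracle", {
  spec <- pedigree_spec(n_families = 2, generations = 3,
                        offspring_per_couple = 2)
  ped <- simulate_pedigree(spec)
  K <- expected_kinship(ped)
  # oracle: drop uniquely labelled founder alleles 10^4 times and count
  # the probability that two random alleles are identical by descent
  founders <- ped$iid[is.na(ped$father)]
  nf <- length(founders); m <- 10000
  fh1 <- matrix(rep(seq(1, 2 * nf, by = 2), m), nf, m,
                dimnames = list(founders, NULL))
  fh2 <- fh1 + 1
  haps <- gene_drop(ped, fh1, fh2, seed = 77)
  n <- nrow(ped)
  phi_hat <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    if (i == j) {
      phi_hat[i, i] <- mean(0.5 + 0.5 * (haps$h1[i, ] == haps$h2[i, ]))
    } else {
      phi_hat[i, j] <- mean((haps$h1[i, ] == haps$h1[j, ]) +
                              (haps$h1[i, ] == haps$h2[j, ]) +
                              (haps$h2[i, ] == haps$h1[j, ]) +
                              (haps$h2[i, ] == haps$h2[j, ])) / 4
      phi_hat[j, i] <- phi_hat[i, j]
    }
  }
  expect_lt(max(abs(2 * phi_hat - K)), 0.03)   # MC error ~ 3-4 SE
})

test_that("expected_kinship is symmetric positive semi-definite", {
  spec <- pedigree_spec(n_families = 6, generations = 3,
                        offspring_per_couple = 3)
  K <- expected_kinship(simulate_pedigree(spec))
  expect_equal(K, t(K))
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
            -1e-10)
})

test_that("phenotype generator honors its variance and effect structure", {
  spec <- pedigree_spec(n_families = 100, generations = 2,
                        offspring_per_couple = 3)
  sim <- simulate_pedigree_genotypes(spec, n_snps = 10, seed = 2)
  n <- nrow(sim$pedigree)
  # fully deterministic null model -> y identically zero
  m0 <- trait_model(mu = 0, beta_age = 0, beta_sex = 0,
                    sigma_g2 = 0, sigma_e2 = 0)
  ph0 <- simulate_phenotype(sim$genotypes, model = m0, seed = 3)
  expect_true(all(ph0$pheno == 0))
  # sigma_g2 = 1, sigma_e2 = 0, K = I -> unit sample variance
  m1 <- trait_model(beta_age = 0, beta_sex = 0, sigma_g2 = 1, sigma_e2 = 0)
  ph1 <- simulate_phenotype(sim$genotypes, K = diag(n), model = m1, seed = 4)
  se <- sqrt(2 / (n - 1))                      # SD of a chi^2 variance est.
  expect_lt(abs(var(ph1$pheno) - 1), 3 * se)
  # planted pair, no noise: conditional mean difference equals 4 * beta
  # (common variants so both product extremes are populated)
  spec_c <- pedigree_spec(n_families = 100, generations = 2,
                          offspring_per_couple = 3,
                          founder_maf_range = c(0.4, 0.5))
  sim_c <- simulate_pedigree_genotypes(spec_c, n_snps = 4, seed = 22)
  m2 <- trait_model(mu = 0, beta_age = 0, beta_sex = 0, sigma_g2 = 0,
                    sigma_e2 = 0,
                    planted_pairs = data.frame(i = 1, j = 2, beta = 1))
  ph2 <- simulate_phenotype(sim_c$genotypes, model = m2, seed = 5)
  prod <- sim_c$genotypes$dosage[, 1] * sim_c$genotypes$dosage[, 2]
  expect_equal(mean(ph2$pheno[prod == 4]) - mean(ph2$pheno[prod == 0]), 4)
  # out-of-range planted index -> configuration error
  m3 <- trait_model(planted_pairs = data.frame(i = 1, j = 99, beta = 1))
  expect_error(simulate_phenotype(sim$genotypes, diag(n), m3, seed = 6),
               class = "epinet_config_error")
})

test_that("spec validation rejects degenerate configurations", {
  expect_error(pedigree_spec(n_families = 0), class = "epinet_config_error")
  expect_error(pedigree_spec(founder_maf_range = c(0, 0.5)),
               class = "epinet_config_error")
  expect_error(pedigree_spec(generations = 0), class = "epinet_config_error")
  expect_error(trait_model(sigma_e2 = -1), class = "epinet_config_error")
  expect_error(trait_model(planted_pairs = data.frame(i = 1, j = 1, beta = 1)),
               class = "epinet_config_error")
})

test_that("block-LD mode creates within-block correlation that survives transmission", {
  spec <- pedigree_spec(n_families = 250, generations = 2,
                        offspring_per_couple = 2)
  sim <- simulate_pedigree_genotypes(spec, n_snps = 20, seed = 8, n_chr = 2,
                                     ld = list(flip_prob = 0.1,
                                               block_size = 10))
  dos <- sim$genotypes$dosage
  offspring <- !is.na(sim$pedigree$father)
  r_within <- cor(dos[offspring, 1], dos[offspring, 2])
  r_between <- abs(cor(dos[offspring, 5], dos[offspring, 15]))
  expect_gt(r_within, 0.5)
  expect_lt(r_between, 0.2)
})

test_that("write_simdata emits a readable, consistent fileset", {
  spec <- pedigree_spec(n_families = 10, generations = 2,
                        offspring_per_couple = 2)
  sim <- simulate_pedigree_genotypes(spec, n_snps = 25, seed = 12)
  model <- trait_model()
  ph <- simulate_phenotype(sim$genotypes, expected_kinship(sim$pedigree),
                           model, seed = 13)
  dir <- withr::local_tempdir()
  paths <- write_simdata(sim, ph, model, dir)
  G2 <- read_plink(sub("\\.bed$", "", paths[["bed"]]))
  expect_equal(G2$dosage, sim$genotypes$dosage, ignore_attr = TRUE)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$sigma_g2, model$sigma_g2)
  expect_equal(truth$seed, 12)
})
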