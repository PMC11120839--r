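# epinet

Genome-wide **epistatic network analysis** of quantitative traits in
family samples.

Single-SNP GWAS of complex neurocognitive traits (the motivating case
is semantic fluency — the number of category members a person can name
in 60 seconds) typically explains little of their moderate
heritability: individual variants have small effects, while pairwise
**epistasis** between loci may carry much of the signal. `epinet`
implements the full discovery-to-replication pipeline for that setting:

1. **Kinship-aware GWAS** — rank-based inverse-normal transform of the
   trait; centered genetic relationship matrix `K = W W'/m`; GLMM
   `y = Xb + g + e`, `g ~ N(0, sigma_g^2 K)` fit by REML (1-D profile
   over `h^2` on the eigenbasis of `K`); per-SNP score tests
   `U = g'Py`, `p = P(chi^2_1 >= U^2 / g'Pg)`.
2. **Pairwise epistasis scan** — after a loose marginal screen
   (p < 0.01) and greedy D' >= 0.9 LD pruning, every SNP pair is fit
   with `y = mu + b_i SNP_i + b_j SNP_j + b_ij (SNP_i x SNP_j) + e`
   (dosages = minor-allele counts 0/1/2), exhaustively, in compiled
   code.
3. **Weighted interaction network** — similarity `-log10 p_ij`
   (max-rescaled), soft-thresholded adjacency, topological overlap
   (TOM), average-linkage clustering with a dynamic-style tree cut into
   color-named modules; each module summarized by its **eigengene**
   (leading PC of standardized module dosages) and tested in the same
   GLMM with age, sex and kinship.
4. **Replication & annotation** — rank-based Wilcoxon set test of a
   module's SNPs in an independent cohort's GWAS (replicated if
   p < 0.01); SNP-to-gene mapping within 50 kb; gene statistic = sum of
   per-SNP 1-df chi-squares (chi-square(n) reference, or an LD-aware
   Monte-Carlo null); hypergeometric gene-set enrichment with BH
   adjustment.

A pedigree-aware simulator (founder haplotypes, Mendelian gene
dropping, optional LD blocks, planted main/interaction effects,
polygenic component proportional to pedigree kinship) makes every stage
testable against ground truth.

## Worked example

Simulate a 250-family discovery cohort (n = 1250) with a planted 12-SNP
hub module — dense pairwise interactions (~45% of trait variance in
total) plus ~1% aligned main effect per hub SNP — among 60 candidate
SNPs, then run the full chain:

```r
library(epinet)

spec <- pedigree_spec(n_families = 250, generations = 2,
                      offspring_per_couple = 3)
sim <- simulate_pedigree_genotypes(spec, n_snps = 60, seed = 42)
K <- expected_kinship(sim$pedigree)

set.seed(43)
planted <- sort(sample(60, 12))
pairs <- t(combn(planted, 2))
signs <- sample(c(-1, 1), nrow(pairs), TRUE)
dos <- sim$genotypes$dosage
comp <- rowSums(sapply(seq_len(nrow(pairs)), function(r)
  signs[r] * dos[, pairs[r, 1]] * dos[, pairs[r, 2]]))
beta <- sqrt(0.45 / 0.55 * 1.15 / var(comp))
maf <- pmin(colMeans(dos) / 2, 1 - colMeans(dos) / 2)
model <- trait_model(
  sigma_g2 = 0.4, sigma_e2 = 0.6,
  planted_pairs = data.frame(i = pairs[, 1], j = pairs[, 2],
                             beta = beta * signs),
  planted_mains = data.frame(snp = planted,
                             beta = sqrt(0.012 * 1.15 /
                                           (2 * maf[planted] * (1 - maf[planted])))))
pheno <- simulate_phenotype(sim$genotypes, K, model, seed = 44)

gw <- run_gwas(sim$genotypes, pheno, K = K)     # INT + REML + score scan
print(gw$null)
#> GLMM null model: n = 1250, h2 = 0.583 (sigma_g2 = 0.5697, sigma_e2 = 0.4081)
#> (Intercept)         age         sex
#>      0.9224     -0.0120      0.0753

y_adj <- residualize(gw$y_int, gw$covariates)
ir <- pairwise_scan(sim$genotypes, y_adj)       # all 1770 pairs
net <- build_network(ir, soft_power = 2)
modules <- detect_modules(net$dissim, min_module_size = 10)
table(modules)
#> modules
#>      grey turquoise
#>        36        24
sum(planted %in% which(modules == "turquoise"))
#> [1] 12                                          # all planted SNPs captured

ME <- module_eigengene(sim$genotypes, modules)
module_association(ME, gw$y_int, gw$covariates, K, modules)
#>      module n_snps coef   se    z        p
#> z turquoise     24 6.05 1.12 5.39 6.97e-08

## replication in an independent cohort drawn from the same truth
sim2 <- simulate_pedigree_genotypes(spec, n_snps = 60, seed = 1042)
pheno2 <- simulate_phenotype(sim2$genotypes, expected_kinship(sim2$pedigree),
                             model, seed = 1044)
gw2 <- run_gwas(sim2$genotypes, pheno2)
replicate_modules(modules, gw2$gwas)
#>      module n_set n_matched alternative        p replicated testable
#> 1 turquoise    24        24       mixed 0.000282       TRUE     TRUE
```

Reading the output: the REML fit attributes ~58% of trait variance to
the kinship random effect (the planted module inflates this beyond the
simulated 0.4); the network stage clusters 24 SNPs into one `turquoise`
module containing all 12 planted hub SNPs; its eigengene is strongly
associated with the trait after adjusting for age, sex and relatedness
(p = 7e-8); and the module's SNPs rank highly in an independent
cohort's GWAS (set-test p = 2.8e-4 < 0.01, i.e., replicated).

The whole chain can also be driven by `run_pipeline(default_config(...))`,
which writes per-stage TSV/JSON artifacts plus a manifest with file
hashes, and `make_report()`, which renders Manhattan/QQ plots, the
chromosome-pair interaction hotspot heatmap and the pseudo-Manhattan of
per-SNP interaction burden.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main end-to-end run from scratch: it simulates
a discovery and a replication family cohort with a planted epistatic
module, executes the full pipeline (QC -> GWAS -> interaction network ->
module replication -> gene scores -> enrichment) under the given seed,
and writes the results JSON.

## Layout

```
R/                  simulator, PLINK I/O + QC, GLMM, network, replication,
                    gene scores, pipeline orchestration
src/                RcppArmadillo pairwise interaction scan
tests/testthat/     unit, property and acceptance tests
scripts/acceptance.R
vignettes/epistatic-network-gwas.Rmd   methods and design notes
```
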