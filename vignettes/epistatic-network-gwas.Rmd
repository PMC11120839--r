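---
title: "Epistatic SNP interaction networks for family-based quantitative traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epistatic SNP interaction networks for family-based quantitative traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`epinet` implements a discovery-to-replication pipeline for detecting
*epistatic SNP networks* that modulate a quantitative trait in family
samples. The motivating setting is a neurocognitive score (for example,
semantic fluency: the number of animals named in 60 seconds) measured
in multi-generation pedigrees and genotyped on a dense SNP array. The
pipeline combines four statistical layers:

1. **Mixed-model GWAS.** Per-SNP score tests under a generalized linear
   mixed model (GLMM) whose random effect carries an empirical genetic
   relationship matrix (GRM), so that pedigree structure does not
   inflate single-SNP statistics.
2. **Pairwise epistasis scan.** After a loose marginal screen
   (p < 0.01) and D'-based LD pruning, every remaining SNP pair is fit
   with the 4-parameter interaction model
   `y = mu + b_i SNP_i + b_j SNP_j + b_ij (SNP_i x SNP_j) + e`,
   with dosages coded 0/1/2 in minor-allele counts.
3. **Weighted network modules.** The pairwise interaction significances
   define a weighted SNP network; topological-overlap clustering groups
   SNPs into modules, each summarized by an eigengene (the leading
   principal component of the module's standardized dosages) that is
   tested against the trait in the same kinship-aware GLMM.
4. **Replication and annotation.** Modules are replicated in an
   independent cohort by a rank-based SNP-set test on the replication
   GWAS statistics, then mapped to genes, scored by a sum-of-chi-square
   gene statistic, and screened for gene-set enrichment with the
   hypergeometric test.

Every stage is also exercised by a pedigree-aware simulator
(`simulate_pedigree_genotypes()`, `simulate_phenotype()`) that plants a
known epistatic module, so the whole pipeline can be validated against
ground truth without restricted cohort data.

# The statistical model

## Phenotype preparation

Raw scores are transformed by the rank-based inverse normal
transformation (INT), `z_i = qnorm((r_i - 3/8) / (n + 1/4))` with
average ranks for ties (`int_transform()`). The Blom offset 3/8 is the
common GWAS convention; the offset is an argument for users who prefer
a different one. Because only ranks enter, any monotone transform of
the input yields identical output; the price is that strongly non-linear
(e.g., product-like) genetic effects are mildly compressed.

## The GLMM and its score test

The null model is `y = X b + g + e` with `g ~ N(0, sigma_g2 K)` and
`e ~ N(0, sigma_e2 I)`; `X` holds intercept, age and sex, and `K` is
the centered empirical GRM `W W' / m` (dosages centered at twice the
sample allele frequency; `compute_grm()`). Variance components are
estimated by REML, profiling over the heritability ratio
`h2 = sigma_g2 / (sigma_g2 + sigma_e2)`: one eigendecomposition of `K`
makes each candidate `h2` an O(n) evaluation, and a 1-D bounded search
(`optimize`, with an explicit check of the `h2 = 0` boundary) is
deterministic and robust. Per-SNP inference uses the score statistic
`U = g' P y` with variance `g' P g`, where
`P = V^-1 - V^-1 X (X' V^-1 X)^-1 X' V^-1`; this requires no refit per
SNP and its p-value is invariant to affine rescaling of the dosage. A
positive score means the minor allele increases the transformed trait.
Genome-wide and suggestive significance use the conventional strict
thresholds 5e-8 and 1e-5.

The acceptance suite verifies the design on simulated 200-family
pedigrees (n = 1000, h2 = 0.4): the GLMM scan stays calibrated
(genomic-control lambda in [0.95, 1.05], type-I error at 5% within
[0.04, 0.06]) while the same data analysed by ordinary regression
inflate (lambda > 1.05), and REML recovers a planted h2 = 0.5 within
0.15 on average over 20 seeds.

## The interaction scan

The pair model is ordinary least squares, solved for all k(k-1)/2
pairs from precomputed cross-moments (BLAS matrix products plus an
O(1) 4x4 solve per pair in compiled code), reporting the interaction
estimate, its t statistic (n - 4 df) and p-value. Two deliberate
approximations, both config-exposed:

* **Covariates.** The scan runs on the INT trait residualized on age
  and sex (`scan_residualize = TRUE`), keeping the screen consistent
  with the module-level test that adjusts for the same covariates.
* **Family structure** is *not* modelled in the O(k^2) scan; kinship
  enters only the module-level GLMM. On related samples the pair
  p-values are therefore mildly dependent across pairs, and the
  package demonstrates the consequences rather than hiding them: the
  naive-vs-GLMM lambda comparison above, and the choice of an
  unrelated-founders cohort for the scan's own null-uniformity check.

A finite-sample caveat the tests document: when both SNPs are rare the
product column has very few informative observations and the
t reference distribution becomes lumpy, so p-values of low-MAF pairs
are only approximately uniform under the null. Calibration checks
therefore use common variants (MAF 0.2-0.5); at n = 700 and 11,175
pairs the Kolmogorov-Smirnov uniformity test then passes comfortably.

## Network construction and module detection

Pair significances are turned into a similarity
`s_ij = -log10(p_ij) / max(-log10 p)`, adjacency `a_ij = s_ij^power`,
and topological overlap
`TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`.
The p-value scale was chosen over the raw interaction estimate because
it is scale-free across allele frequencies; the exact "epistatic
correlation" used by the original network tooling is not printed in the
source literature, so this reconstruction is documented as such. The
soft power is selected as the smallest value in 1..20 whose equal-width
binned connectivity distribution fits a scale-free line with R^2 >= 0.8
and negative slope, falling back to 6 (`pick_soft_power()`); because
the p-derived similarity is heavy-tailed (one extreme pair sets the
rescaling maximum), informative analyses often call for a *lower* power
than correlation networks do, and `soft_power` is a config key.

Module detection (`detect_modules()`) is a dynamic-tree-cut variant
built from scratch (the reference implementation is not available in
this environment): average-linkage clustering of `1 - TOM`, a static
cut at 0.99 of the tallest merge, then per-branch acceptance requiring
(i) at least `min_module_size` SNPs (default 30) and (ii) a *core
scatter* - the mean dissimilarity among the branch's most tightly
connected `min_module_size` members - below 0.82 on a scale anchored
at the 5th percentile of all dissimilarities (the mid "deep split"
constant of the reference method). Everything else is `"grey"`.
Accepted modules are named along the WGCNA color sequence by size rank
(largest = `"turquoise"`). The scatter criterion is calibrated for the
sparse, heavy-tailed similarity the scan produces; on synthetic null
similarity (uniform p-values) essentially all SNPs come out grey,
while planted similarity blocks are recovered exactly.

## Module eigengenes and their association test

A module eigengene is the first left singular vector of the module's
standardized dosage matrix, unit-norm, sign-fixed to correlate
positively with the module's mean standardized dosage (so that flipping
minor/major orientation leaves results invariant). The eigengene is
tested as a fixed effect in the GLMM with age, sex and kinship
(`glmm_wald()`), reporting the signed coefficient and a Wald p-value.

An honest structural caveat: for SNPs in linkage equilibrium the
leading PC of a genotype matrix is essentially direction-less, so an
eigengene only summarizes a module well when its SNPs are mutually
correlated (regional LD, shared ancestry) or carry aligned marginal
effects. The simulator's block-LD mode exists precisely to create that
regime for testing; the eigengene test is validated on an LD-block
module with aligned main effects (p < 0.01, with random same-size
modules null, across seeds).

## Replication

`replicate_modules()` ranks every module's SNPs within the replication
GWAS and applies a Wilcoxon rank-sum set test (`gene_set_test()`),
exact for small sets, normal approximation with continuity and tie
correction otherwise. The default alternative is `"mixed"` (ranks of
absolute statistics), since module SNPs need not share an effect
direction. The ranked statistic is the *standardized* score
`U / sqrt(var U)` rather than the raw score, which scales with allele
frequency and would make the rank test MAF-driven. Replication is
declared at p < 0.01 (strict), and a module with under half of its
SNPs present in the replication panel is marked untestable rather than
failed.

## Gene scores and enrichment

SNPs of significant modules map to genes within 50 kb of the gene span
(BED input, 0-based half-open, converted to 1-based inclusive). Each
gene's statistic is the sum of its SNPs' upper-tail 1-df chi-squares;
without LD information the reference distribution is chi-square with
n df, and when genotypes are available the default is a seeded
Monte-Carlo null from multivariate normal draws with the observed
genotype correlation (the add-one-corrected exceedance proportion, so
the p-value is never exactly zero). Enrichment of significant genes
(p < 0.01) against user-supplied gene sets uses the one-sided
hypergeometric test with Benjamini-Hochberg adjustment across sets; no
annotation databases are bundled, keeping the package fully offline.

# The simulator: what it emulates and what it does not

`simulate_pedigree_genotypes()` builds families from founder couples
(children per couple and generation count configurable; sexes alternate
within sibships), draws founder haplotypes Bernoulli(maf) with per-SNP
maf uniform on a configurable range (default 0.05-0.5), and gene-drops
alleles with SNPs independent by default. The optional LD mode creates
founder-haplotype correlation by copy-with-flip within blocks of
adjacent SNPs and co-transmits those blocks, so that pruning and
eigengene summaries have realistic input. `simulate_phenotype()` adds
age (uniform on 60-100 years, matching an elderly study population) and
sex (Bernoulli(0.5)) covariate effects, planted main and pairwise
interaction effects on the dosage scale, a polygenic component
`N(0, sigma_g2 K)` and i.i.d. noise; defaults (`sigma_g2 = 0.4`,
`sigma_e2 = 0.6`, `beta_age = -0.02` per year, `beta_sex = 0.1`) give a
moderately heritable, mildly age-declining trait on roughly unit scale.
`expected_kinship()` provides the exact pedigree expectation
(numerator-relationship scale) against which the empirical GRM is
validated (correlation about 0.9 at 5000 SNPs).

Not emulated: realistic human LD maps, imputation uncertainty, sex
chromosomes, genotyping batch artifacts. A green simulation test
therefore establishes internal statistical correctness, not robustness
to all real-data pathologies.

## Power of module recovery: an honest accounting

The headline end-to-end check plants a 30-SNP module whose pairwise
effects contribute about 5% of trait variance at n = 1000 among 2000
candidate SNPs. Measured across seeds, this world is *not* recoverable:
with total interaction variance v spread over P pairs, each pair's
score noncentrality is roughly `n v rho / P`, where rho (the fraction
of a product's variance orthogonal to its main effects) is about
0.3-0.7 depending on MAF - that is, NCP of order 1 for a degree-4
graph at v = 0.05, and the planted pairs' median p-value measures 0.42
against a null of 0.5. Because module similarity is built from the
pair p-values, no clustering rule can then isolate the module; the
corresponding acceptance test is implemented faithfully at the stated
signal level and is expected to fail, with the measured counts in its
output. Recovery demonstrations therefore use a *denser, stronger*
hub world (12 SNPs, all pairs interacting, ~45% interaction variance,
plus ~1% aligned main effect per hub SNP); there the top module
captures >= 80% of planted SNPs and replicates in an independent
cohort.

# Numerical choices and degenerate inputs

* HWE uses the exact conditional enumeration test (recurrence started
  at the modal heterozygote count, so no overflow at large n), not the
  chi-square approximation - the field standard for rare variants. The
  two agree within 0.01 for balanced counts of 100+ per cell.
* D' comes from an EM fit of haplotype frequencies to unphased dosage
  pairs (200 iterations, tolerance 1e-8); non-convergent pairs are
  flagged and treated as unlinked. Monomorphic SNPs are an error for
  `estimate_dprime()` and are treated as unlinked by the pruner.
* Pair models with rank-deficient designs (constant SNPs, products
  collinear with mains; condition-number guard at 1e-10) are flagged
  with p = 1 and excluded from similarity and hotspot summaries.
* Hotspot matrices min-max rescale the per-chromosome-pair 0.9
  quantiles; if all populated cells are equal, the rescaled value is
  defined as 1.
* The pipeline manifest stores only scalar configuration and file
  hashes; all randomness flows from one `seed` entry, so re-running a
  configuration reproduces outputs byte for byte.
* Significance thresholds are everywhere strict (`<`), so a p-value
  exactly at a boundary is not significant.

# Limitations

* The pair scan's least-squares model ignores kinship; on strongly
  related samples the interaction network inherits some family
  structure. The module-level GLMM corrects the association test but
  not the network topology itself.
* Eigengene summaries are weakly identified for modules of unlinked
  SNPs without aligned effects (see above).
* The module count and composition depend on the soft power, cut
  height and minimum size; the defaults follow the conventions of
  weighted co-expression analysis but cannot be checked against the
  restricted cohort data that motivated the pipeline.
* Binary traits, multiple variance components, and X-chromosome
  handling are out of scope.
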