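#' Pedigree simulation specification
#'
#' Describes the family structure and founder allele-frequency spectrum
#' used by [simulate_pedigree_genotypes()]. Families are built from a
#' founder couple; each couple has `offspring_per_couple` children and,
#' in every generation except the last, each child marries a new founder
#' so that the pedigree deepens without inbreeding.
#'
#' @param n_families number of independent families.
#' @param generations number of generations (>= 1; 1 = founders only).
#' @param offspring_per_couple children per couple.
#' @param founder_maf_range length-2 numeric, lower/upper bound of the
#'   uniform founder minor-allele-frequency spectrum, in (0, 0.5].
#' @return A `pedigree_spec` list.
#' @export
pedigree_spec <- function(n_families = 200, generations = 2,
                          offspring_per_couple = 3,
                          founder_maf_range = c(0.05, 0.5)) {
  if (n_families < 1) stop_config("n_families must be >= 1")
  if (generations < 1) stop_config("generations must be >= 1")
  if (generations > 1 && offspring_per_couple < 1)
    stop_config("offspring_per_couple must be >= 1")
  if (length(founder_maf_range) != 2 || founder_maf_range[1] <= 0 ||
      founder_maf_range[2] > 0.5 || founder_maf_range[1] > founder_maf_range[2])
    stop_config("founder_maf_range must lie in (0, 0.5] with lower <= upper")
  structure(list(n_families = as.integer(n_families),
                 generations = as.integer(generations),
                 offspring_per_couple = as.integer(offspring_per_couple),
                 founder_maf_range = as.numeric(founder_maf_range)),
            class = "pedigree_spec")
}

#' Trait-generating model
#'
#' Generative model for a quantitative trait on a pedigree:
#' `y = mu + beta_age*age + beta_sex*sex + sum(main effects) +
#'  sum(beta_ij * SNP_i * SNP_j) + g + e`, with polygenic
#' `g ~ MVN(0, sigma_g2 * K)` and residual `e ~ N(0, sigma_e2)`.
#' SNP dosages enter as minor-allele counts, and the pairwise product
#' term is the statistical epistasis the downstream network scan is
#' designed to recover.
#'
#' @param mu intercept.
#' @param beta_age fixed effect per year of age.
#' @param beta_sex fixed effect of sex (coded 0/1).
#' @param sigma_g2 polygenic variance (propagated through the kinship).
#' @param sigma_e2 residual variance (> 0 unless the trait is fully
#'   deterministic, in which case 0 is allowed for oracle tests).
#' @param planted_pairs data.frame with columns `i`, `j`, `beta`:
#'   SNP column indices (distinct within a pair) and interaction effect.
#' @param planted_mains data.frame with columns `snp`, `beta`.
#' @return A `trait_model` list.
#' @export
trait_model <- function(mu = 0, beta_age = -0.02, beta_sex = 0.1,
                        sigma_g2 = 0.4, sigma_e2 = 0.6,
                        planted_pairs = NULL, planted_mains = NULL) {
  if (sigma_g2 < 0) stop_config("sigma_g2 must be >= 0")
  if (sigma_e2 < 0) stop_config("sigma_e2 must be >= 0")
  if (!is.null(planted_pairs)) {
    planted_pairs <- as.data.frame(planted_pairs)
    if (!all(c("i", "j", "beta") %in% names(planted_pairs)))
      stop_config("planted_pairs needs columns i, j, beta")
    if (any(planted_pairs$i == planted_pairs$j))
      stop_config("planted pair members must be distinct SNPs")
  }
  if (!is.null(planted_mains)) {
    planted_mains <- as.data.frame(planted_mains)
    if (!all(c("snp", "beta") %in% names(planted_mains)))
      stop_config("planted_mains needs columns snp, beta")
  }
  structure(list(mu = mu, beta_age = beta_age, beta_sex = beta_sex,
                 sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 planted_pairs = planted_pairs, planted_mains = planted_mains),
            class = "trait_model")
}

#' Build the pedigree table for a specification
#'
#' Deterministic family layout: generation 1 is a founder couple; each
#' couple has `offspring_per_couple` children; in all but the last
#' generation every child marries a founder brought into the family.
#' Sexes alternate within sibships (expected sex ratio 1:1); married-in
#' founders take the opposite sex.
#'
#' @param spec a [pedigree_spec()].
#' @return data.frame with columns `fid`, `iid`, `father`, `mother`
#'   (`NA` for founders), `sex` (1 = male, 2 = female), `generation`.
#'   Parents always precede their offspring.
#' @export
simulate_pedigree <- function(spec) {
  stopifnot(inherits(spec, "pedigree_spec"))
  rows <- vector("list", spec$n_families)
  for (f in seq_len(spec$n_families)) {
    fid <- sprintf("fam%04d", f)
    id <- function(k) sprintf("%s_i%03d", fid, k)
    k <- 0L
    nxt <- function() { k <<- k + 1L; id(k) }
    tab <- data.frame(fid = character(), iid = character(),
                      father = character(), mother = character(),
                      sex = integer(), generation = integer(),
                      stringsAsFactors = FALSE)
    add <- function(iid, father, mother, sex, gen) {
      tab[nrow(tab) + 1L, ] <<- list(fid, iid, father, mother, sex, gen)
    }
    pa <- nxt(); ma <- nxt()
    add(pa, NA_character_, NA_character_, 1L, 1L)
    add(ma, NA_character_, NA_character_, 2L, 1L)
    couples <- list(c(pa, ma))
    if (spec$generations > 1) {
      for (g in 2:spec$generations) {
        newcouples <- list()
        for (cp in couples) {
          for (ch in seq_len(spec$offspring_per_couple)) {
            child <- nxt()
            csex <- if (ch %% 2L == 1L) 1L else 2L
            add(child, cp[1], cp[2], csex, g)
            if (g < spec$generations) {
              sp <- nxt()
              add(sp, NA_character_, NA_character_,
                  if (csex == 1L) 2L else 1L, g)
              newcouples[[length(newcouples) + 1L]] <-
                if (csex == 1L) c(child, sp) else c(sp, child)
            }
          }
        }
        couples <- newcouples
      }
    }
    rows[[f]] <- tab
  }
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  ped
}

#' Drop founder haplotypes through a pedigree
#'
#' Mendelian transmission: every non-founder receives one allele from
#' each parent; by default each SNP segregates independently (free
#' recombination). If `block_size > 1`, the transmitted parental
#' haplotype is chosen once per block of adjacent SNPs, which preserves
#' founder linkage disequilibrium within blocks across generations.
#'
#' @param pedigree pedigree table as from [simulate_pedigree()].
#' @param founder_h1,founder_h2 0/1 matrices (founders x SNPs) of founder
#'   haplotypes, rows named by founder iid.
#' @param seed integer RNG seed for transmission draws.
#' @param block_size number of adjacent SNPs co-transmitted (1 = SNPs
#'   independent).
#' @return list of 0/1 matrices `h1`, `h2` (all individuals x SNPs),
#'   paternal and maternal haplotypes.
#' @export
gene_drop <- function(pedigree, founder_h1, founder_h2, seed,
                      block_size = 1L) {
  m <- ncol(founder_h1)
  n <- nrow(pedigree)
  set.seed(seed)
  h1 <- matrix(0L, n, m, dimnames = list(pedigree$iid, NULL))
  h2 <- h1
  founder <- is.na(pedigree$father)
  h1[pedigree$iid[founder], ] <- founder_h1[pedigree$iid[founder], ]
  h2[pedigree$iid[founder], ] <- founder_h2[pedigree$iid[founder], ]
  blk <- rep(seq_len(ceiling(m / block_size)), each = block_size)[seq_len(m)]
  nblk <- max(blk)
  row_of <- stats::setNames(seq_len(n), pedigree$iid)
  transmit <- function(p) {
    sel <- stats::rbinom(nblk, 1L, 0.5)[blk]
    sel * h1[p, ] + (1L - sel) * h2[p, ]
  }
  for (i in which(!founder)) {
    fa <- row_of[[pedigree$father[i]]]
    mo <- row_of[[pedigree$mother[i]]]
    if (fa >= i || mo >= i)
      stop_pedigree("parents must precede offspring in the pedigree table")
    h1[i, ] <- transmit(fa)
    h2[i, ] <- transmit(mo)
  }
  list(h1 = h1, h2 = h2)
}

#' Simulate pedigree-structured genotypes
#'
#' Founder haplotype alleles are drawn Bernoulli(maf) per SNP with
#' per-SNP maf uniform on `spec$founder_maf_range`; non-founders are
#' filled in by gene dropping. Optional linkage disequilibrium is
#' created by a copy-with-flip process along founder haplotypes within
#' blocks of adjacent SNPs, and those blocks are co-transmitted.
#'
#' @param spec a [pedigree_spec()].
#' @param n_snps number of SNPs (assigned contiguously to chromosomes
#'   1..`n_chr`, positions evenly spaced).
#' @param seed integer RNG seed; identical seeds give identical output.
#' @param ld `NULL` for linkage equilibrium, or
#'   `list(flip_prob =, block_size =)`: within a block each founder
#'   allele copies its left neighbour with probability `1 - flip_prob`.
#' @param missing_rate fraction of dosage calls set missing at random.
#' @param n_chr number of chromosomes to spread SNPs over.
#' @return list with `genotypes` (a [genotype_matrix()]), `pedigree`
#'   (with the simulation `seed` as attribute), and `founder_maf`.
#' @export
simulate_pedigree_genotypes <- function(spec, n_snps, seed, ld = NULL,
                                        missing_rate = 0, n_chr = 22L) {
  stopifnot(inherits(spec, "pedigree_spec"))
  if (n_snps < 1) stop_config("n_snps must be >= 1")
  ped <- simulate_pedigree(spec)
  set.seed(seed)
  m <- as.integer(n_snps)
  maf <- stats::runif(m, spec$founder_maf_range[1], spec$founder_maf_range[2])
  n_chr <- min(n_chr, m)
  chr <- rep(seq_len(n_chr), each = ceiling(m / n_chr))[seq_len(m)]
  pos <- integer(m)
  for (c in unique(chr)) pos[chr == c] <- seq_len(sum(chr == c)) * 5000L
  founder_ids <- ped$iid[is.na(ped$father)]
  nf <- length(founder_ids)
  block_size <- 1L
  if (is.null(ld)) {
    fh1 <- matrix(stats::rbinom(nf * m, 1L, rep(maf, each = nf)), nf, m)
    fh2 <- matrix(stats::rbinom(nf * m, 1L, rep(maf, each = nf)), nf, m)
  } else {
    block_size <- as.integer(ld$block_size %||% 10L)
    flip <- ld$flip_prob %||% 0.1
    gen_haps <- function() {
      h <- matrix(0L, nf, m)
      h[, 1] <- stats::rbinom(nf, 1L, maf[1])
      for (j in 2:m) {
        new_block <- ((j - 1L) %% block_size == 0L) || chr[j] != chr[j - 1L]
        if (new_block) {
          h[, j] <- stats::rbinom(nf, 1L, maf[j])
        } else {
          keep <- stats::rbinom(nf, 1L, 1 - flip)
          h[, j] <- keep * h[, j - 1L] + (1L - keep) * stats::rbinom(nf, 1L, maf[j])
        }
      }
      h
    }
    fh1 <- gen_haps(); fh2 <- gen_haps()
  }
  rownames(fh1) <- rownames(fh2) <- founder_ids
  haps <- gene_drop(ped, fh1, fh2, seed = derive_seed(seed, 1L),
                    block_size = block_size)
  dosage <- haps$h1 + haps$h2
  if (missing_rate > 0) {
    set.seed(derive_seed(seed, 2L))
    dosage[stats::runif(length(dosage)) < missing_rate] <- NA
  }
  snps <- data.frame(snp_id = sprintf("snp%06d", seq_len(m)),
                     chr = chr, pos = pos,
                     allele_minor = "A", allele_major = "G",
                     stringsAsFactors = FALSE)
  G <- genotype_matrix(dosage, snps, samples = ped$iid)
  attr(ped, "seed") <- seed
  list(genotypes = G, pedigree = ped, founder_maf = maf)
}

#' Expected (pedigree-based) kinship
#'
#' Recursive kinship coefficients from pedigree structure, returned on
#' the numerator-relationship scale (2 x kinship), so non-inbred
#' individuals have diagonal 1 and full sibs share 0.5. This is the
#' ground truth against which the empirical GRM can be validated.
#'
#' @param pedigree pedigree table (`iid`, `father`, `mother`; `NA`
#'   parents for founders). Rows are re-ordered internally so parents
#'   precede offspring; a cyclic pedigree (individual its own ancestor)
#'   is an error.
#' @return symmetric n x n matrix with dimnames = iid.
#' @export
expected_kinship <- function(pedigree) {
  ped <- as.data.frame(pedigree)
  n <- nrow(ped)
  ord <- integer(0)
  placed <- logical(n)
  names(placed) <- ped$iid
  repeat {
    ready <- !placed &
      (is.na(ped$father) | placed[ped$father]) &
      (is.na(ped$mother) | placed[ped$mother])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[which(ready)] <- TRUE
  }
  if (length(ord) < n)
    stop_pedigree("pedigree is cyclic or references unknown parents")
  ped <- ped[ord, ]
  idx <- stats::setNames(seq_len(n), ped$iid)
  fa <- ifelse(is.na(ped$father), 0L, idx[ped$father])
  mo <- ifelse(is.na(ped$mother), 0L, idx[ped$mother])
  phi <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (fa[i] == 0L) {
      phi[i, i] <- 0.5
    } else {
      phi[i, i] <- 0.5 * (1 + phi[fa[i], mo[i]])
      if (i > 1) {
        j <- seq_len(i - 1L)
        phi[i, j] <- 0.5 * (phi[fa[i], j] + phi[mo[i], j])
        phi[j, i] <- phi[i, j]
      }
    }
  }
  K <- 2 * phi
  dimnames(K) <- list(ped$iid, ped$iid)
  # restore caller's row order
  K[pedigree$iid, pedigree$iid]
}

#' Simulate a quantitative phenotype on a pedigree
#'
#' Applies the generative model of [trait_model()] to simulated
#' genotypes: covariate effects, planted main and pairwise-interaction
#' effects, a polygenic component with covariance `sigma_g2 * K`, and
#' i.i.d. residual noise. Missing dosages are mean-imputed for effect
#' computation only.
#'
#' @param G a [genotype_matrix()].
#' @param K kinship matrix aligned to `G$samples` (ignored when
#'   `sigma_g2 = 0`).
#' @param model a [trait_model()].
#' @param covariates optional data.frame with columns `age`, `sex`
#'   (0/1); when `NULL`, age ~ Uniform(60, 100) and sex ~ Bernoulli(0.5)
#'   are drawn.
#' @param seed integer RNG seed.
#' @return data.frame (`iid`, `pheno`, `age`, `sex`); attribute
#'   `"components"` holds the generative pieces for validation.
#' @export
simulate_phenotype <- function(G, K = NULL, model = trait_model(),
                               covariates = NULL, seed = 1L) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(model, "trait_model"))
  n <- nrow(G$dosage); m <- ncol(G$dosage)
  set.seed(seed)
  if (is.null(covariates)) {
    covariates <- data.frame(age = stats::runif(n, 60, 100),
                             sex = stats::rbinom(n, 1L, 0.5))
  }
  if (nrow(covariates) != n) stop_config("covariates must match samples")
  dos <- impute_mean(G$dosage)
  main_eff <- numeric(n); epi_eff <- numeric(n)
  if (!is.null(model$planted_mains)) {
    pm <- model$planted_mains
    if (any(pm$snp < 1 | pm$snp > m))
      stop_config("planted main SNP index out of range")
    for (r in seq_len(nrow(pm)))
      main_eff <- main_eff + pm$beta[r] * dos[, pm$snp[r]]
  }
  if (!is.null(model$planted_pairs)) {
    pp <- model$planted_pairs
    if (any(c(pp$i, pp$j) < 1 | c(pp$i, pp$j) > m))
      stop_config("planted pair SNP index out of range")
    for (r in seq_len(nrow(pp)))
      epi_eff <- epi_eff + pp$beta[r] * dos[, pp$i[r]] * dos[, pp$j[r]]
  }
  g <- numeric(n)
  if (model$sigma_g2 > 0) {
    if (is.null(K)) stop_config("K required when sigma_g2 > 0")
    eig <- eigen(K, symmetric = TRUE)
    g <- sqrt(model$sigma_g2) *
      drop(eig$vectors %*% (sqrt(pmax(eig$values, 0)) * stats::rnorm(n)))
  }
  e <- if (model$sigma_e2 > 0) stats::rnorm(n, sd = sqrt(model$sigma_e2)) else numeric(n)
  y <- model$mu + model$beta_age * covariates$age +
    model$beta_sex * covariates$sex + main_eff + epi_eff + g + e
  out <- data.frame(iid = G$samples, pheno = y,
                    age = covariates$age, sex = covariates$sex,
                    stringsAsFactors = FALSE)
  attr(out, "components") <- list(main = main_eff, epistatic = epi_eff,
                                  polygenic = g, residual = e, seed = seed)
  out
}

#' Write a simulated data set to disk
#'
#' Emits PLINK bed/bim/fam, a phenotype TSV (`iid`, `pheno`, `age`,
#' `sex`), a pedigree TSV (`iid`, `father`, `mother`, `sex`) and a truth
#' JSON recording planted effects, variance components and the seed.
#'
#' @param sim output of [simulate_pedigree_genotypes()].
#' @param phenotype output of [simulate_phenotype()].
#' @param model the [trait_model()] used.
#' @param dir output directory (created if needed).
#' @param basename file stem for the PLINK triplet.
#' @return invisibly, the named vector of paths written.
#' @export
write_simdata <- function(sim, phenotype, model, dir, basename = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, basename)
  write_plink(sim$genotypes, stem, pedigree = sim$pedigree)
  pheno_path <- file.path(dir, paste0(basename, "_pheno.tsv"))
  utils::write.table(phenotype, pheno_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ped_path <- file.path(dir, paste0(basename, "_pedigree.tsv"))
  utils::write.table(sim$pedigree[, c("iid", "father", "mother", "sex")],
                     ped_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_path <- file.path(dir, paste0(basename, "_truth.json"))
  truth <- list(seed = attr(sim$pedigree, "seed"),
                mu = model$mu, beta_age = model$beta_age,
                beta_sex = model$beta_sex,
                sigma_g2 = model$sigma_g2, sigma_e2 = model$sigma_e2,
                planted_pairs = model$planted_pairs,
                planted_mains = model$planted_mains)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(bed = paste0(stem, ".bed"), pheno = pheno_path,
              pedigree = ped_path, truth = truth_path))
}
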