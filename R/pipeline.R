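# End-to-end orchestration: qc -> gwas -> network -> replication ->
# gene scoring -> enrichment, with a JSON manifest of every artifact.

#' Default pipeline configuration
#'
#' All thresholds default to the values used throughout the package's
#' documentation: maf 0.01, HWE 1e-6, GWAS candidate filter 0.01,
#' D' 0.9 with block size 1000, genome-wide 5e-8 and suggestive 1e-5
#' significance, module / replication / gene p 0.01, gene window 50 kb.
#'
#' @param ... named overrides of any configuration entry.
#' @return named list of class `epinet_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    # inputs: PLINK stem or in-memory genotype_matrix / data.frame
    genotypes = NULL, phenotype = NULL, kinship = NULL,
    rep_genotypes = NULL, rep_phenotype = NULL,
    annotation = NULL, gene_sets = NULL,
    # thresholds
    maf_min = 0.01, hwe_p_min = 1e-6,
    gwas_p_cut = 0.01,
    dprime_min = 0.9, max_block = 1000L,
    gw_threshold = 5e-8, suggestive_threshold = 1e-5,
    soft_power = NULL, min_module_size = 30L,
    module_p = 0.01, replication_p = 0.01,
    gene_window = 50000L, gene_p = 0.01,
    scan_residualize = TRUE, gene_test_ld = TRUE,
    gene_test_nsim = 1e5,
    # bookkeeping
    seed = 1L, out_dir = NULL, write_grm = TRUE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop_config(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, class = c("epinet_config", "list"))
}

load_genotypes <- function(x) {
  if (inherits(x, "genotype_matrix")) return(x)
  if (is.character(x)) return(read_plink(x))
  stop_data("genotypes must be a PLINK stem or a genotype_matrix")
}

load_phenotype <- function(x) {
  if (is.data.frame(x)) ph <- x
  else if (is.character(x))
    ph <- utils::read.table(x, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  else stop_data("phenotype must be a TSV path or a data.frame")
  need <- c("iid", "pheno", "age", "sex")
  miss <- setdiff(need, names(ph))
  if (length(miss))
    stop_data(paste("phenotype table missing column(s):",
                    paste(miss, collapse = ", ")))
  ph
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full discovery-to-annotation pipeline
#'
#' Stages: `qc` (MAF + HWE filters), `gwas` (GRM, GLMM null model,
#' score scan), `episnet` (GWAS filter, LD pruning, pairwise scan,
#' network modules, eigengene association), optional `replicate`
#' (rank-based set test in an independent cohort), `genes`
#' (SNP-to-gene mapping and sum-of-chi-square tests for significant
#' modules) and `enrich` (hypergeometric enrichment of significant
#' genes). Any stage failure aborts with the stage name. Re-running
#' with an identical configuration and seed reproduces byte-identical
#' outputs.
#'
#' @param config an [default_config()] list; `out_dir` is required.
#' @return the run manifest (invisibly also written as
#'   `manifest.json`): per-stage status, output paths and md5 hashes.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "epinet_config")) config
         else do.call(default_config, config)
  if (is.null(cfg$out_dir)) stop_config("config$out_dir is required")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  manifest <- list(package_version = as.character(utils::packageVersion("epinet")),
                   seed = cfg$seed, stages = list())
  paths <- character(0)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop_data(sprintf("pipeline stage '%s' failed: %s", name,
                        conditionMessage(e)))
    })
    manifest$stages[[name]] <<- list(status = "complete",
                                     outputs = as.list(res))
    paths <<- c(paths, unlist(res))
    res
  }

  # qc -----------------------------------------------------------------
  env <- new.env()
  stage("qc", {
    env$G_raw <- load_genotypes(cfg$genotypes)
    env$pheno <- load_phenotype(cfg$phenotype)
    qc <- qc_genotypes(env$G_raw, maf_min = cfg$maf_min,
                       hwe_p_min = cfg$hwe_p_min)
    env$G <- qc$genotypes
    jsonlite::write_json(qc$report, out("qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
    list(qc_report = out("qc_report.json"))
  })

  # gwas ---------------------------------------------------------------
  stage("gwas", {
    K <- cfg$kinship
    if (is.character(K)) K <- as.matrix(utils::read.table(K))
    gw <- run_gwas(env$G, env$pheno, K = K)
    env$gw <- gw
    gtab <- gw$gwas
    gtab$significance <- classify_significance(gtab$p, cfg$gw_threshold,
                                               cfg$suggestive_threshold)
    res <- list(gwas = write_tsv(gtab, out("gwas.tsv")))
    if (isTRUE(cfg$write_grm)) {
      utils::write.table(format(gw$K, digits = 10), out("grm.txt"),
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
      res$grm <- out("grm.txt")
    }
    res
  })

  # episnet ------------------------------------------------------------
  stage("episnet", {
    idx <- filter_by_gwas(env$gw$gwas, cfg$gwas_p_cut)
    Gf <- subset_snps(env$G, idx)
    tags <- ld_prune(Gf, dprime_min = cfg$dprime_min,
                     max_block = cfg$max_block)
    Gp <- subset_snps(Gf, tags)
    env$Gp <- Gp
    y_adj <- if (isTRUE(cfg$scan_residualize))
      residualize(env$gw$y_int, env$gw$covariates) else env$gw$y_int
    ir <- pairwise_scan(Gp, y_adj)
    hot <- interaction_hotspots(ir, Gp$snps)
    sums <- sum_effect_sizes(ir)
    net <- build_network(ir, soft_power = cfg$soft_power)
    labels <- detect_modules(net$dissim,
                             min_module_size = cfg$min_module_size)
    env$labels <- labels
    mods_present <- length(setdiff(unique(labels), "grey")) > 0
    if (mods_present) {
      ME <- module_eigengene(Gp, labels)
      assoc <- module_association(ME, env$gw$y_int, env$gw$covariates,
                                  env$gw$K, labels)
      me_tab <- data.frame(iid = rownames(ME), ME, check.names = FALSE)
    } else {
      assoc <- data.frame(module = character(), n_snps = integer(),
                          coef = numeric(), se = numeric(), z = numeric(),
                          p = numeric())
      me_tab <- data.frame(iid = Gp$samples)
    }
    env$assoc <- assoc
    utils::write.csv(round(hot, 6), out("hotspots.csv"))
    list(pairs = write_tsv(ir[, c("snp_i", "snp_j", "beta", "t", "p")],
                           out("interaction_pairs.tsv")),
         modules = write_tsv(data.frame(snp_id = names(labels),
                                        module = as.character(labels)),
                             out("module_assignment.tsv")),
         eigengenes = write_tsv(me_tab, out("module_eigengenes.tsv")),
         module_stats = write_tsv(assoc, out("module_stats.tsv")),
         hotspots = out("hotspots.csv"),
         effect_sums = write_tsv(data.frame(snp_id = names(sums),
                                            sum_neglogp = as.numeric(sums)),
                                 out("interaction_sums.tsv")))
  })

  sig_mods <- env$assoc$module[env$assoc$p < cfg$module_p]

  # replicate (optional) ------------------------------------------------
  if (!is.null(cfg$rep_genotypes)) {
    stage("replicate", {
      if (any(env$labels != "grey")) {
        Gr <- load_genotypes(cfg$rep_genotypes)
        phr <- load_phenotype(cfg$rep_phenotype)
        qcr <- qc_genotypes(Gr, maf_min = cfg$maf_min,
                            hwe_p_min = cfg$hwe_p_min)
        gwr <- run_gwas(qcr$genotypes, phr)
        rep_tab <- replicate_modules(env$labels, gwr$gwas,
                                     threshold = cfg$replication_p)
      } else {
        rep_tab <- data.frame(module = character(), n_set = integer(),
                              n_matched = integer(),
                              alternative = character(), p = numeric(),
                              replicated = logical(), testable = logical())
      }
      list(replication = write_tsv(rep_tab, out("replication.tsv")))
    })
  }

  # genes + enrichment (optional) ---------------------------------------
  if (!is.null(cfg$annotation)) {
    stage("genes", {
      genes <- if (is.data.frame(cfg$annotation)) cfg$annotation
               else read_gene_bed(cfg$annotation)
      snps_in <- env$Gp$snps[env$labels[env$Gp$snps$snp_id] %in% sig_mods, ,
                             drop = FALSE]
      if (!nrow(snps_in)) snps_in <- env$Gp$snps[0, ]
      mapping <- map_snps_to_genes(snps_in, genes, window = cfg$gene_window)
      gt <- if (nrow(mapping))
        gene_tests(mapping, env$gw$gwas,
                   G = if (isTRUE(cfg$gene_test_ld)) env$Gp else NULL,
                   n_sim = cfg$gene_test_nsim, seed = cfg$seed)
      else data.frame(gene_id = character(), n_snps = integer(),
                      stat = numeric(), p = numeric(), method = character())
      env$gene_tab <- gt
      list(genes = write_tsv(gt, out("genes.tsv")))
    })
    if (!is.null(cfg$gene_sets)) {
      stage("enrich", {
        sets <- if (is.list(cfg$gene_sets) && !is.data.frame(cfg$gene_sets))
          cfg$gene_sets else read_gmt(cfg$gene_sets)
        gt <- env$gene_tab
        sel <- gt$gene_id[gt$p < cfg$gene_p]
        en <- if (nrow(gt))
          enrich(sel, sets, background = gt$gene_id)
        else data.frame(set = character(), n_set = integer(),
                        overlap = integer(), expected = numeric(),
                        fold = numeric(), p = numeric(), p_adj = numeric())
        list(enrichment = write_tsv(en, out("enrichment.tsv")))
      })
    }
  }

  manifest$hashes <- as.list(tools::md5sum(paths))
  # manifest keeps the scalar configuration (thresholds, seed), not the
  # in-memory data objects
  manifest$config <- cfg[vapply(cfg, function(x)
    is.atomic(x) && length(x) == 1L, TRUE)]
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}

#' Generate report figures and tables from a pipeline run
#'
#' Emits a Manhattan plot (with genome-wide and suggestive threshold
#' lines), a QQ plot annotated with the genomic-inflation lambda, the
#' chromosome-pair hotspot heatmap, a pseudo-Manhattan of per-SNP
#' interaction totals, and copies of the module and replication tables.
#' Figures for missing stage outputs are skipped with a warning.
#'
#' @param out_dir directory of a completed [run_pipeline()] run.
#' @param format `"pdf"` (default, always available) or `"png"`.
#' @param gw_threshold,suggestive_threshold significance lines for the
#'   Manhattan plot.
#' @return named character vector of the files written.
#' @export
make_report <- function(out_dir, format = c("pdf", "png"),
                        gw_threshold = 5e-8, suggestive_threshold = 1e-5) {
  format <- match.arg(format)
  open_dev <- function(path) {
    if (format == "png") grDevices::png(path, width = 900, height = 600)
    else grDevices::pdf(path, width = 9, height = 6)
  }
  ext <- function(stem) file.path(out_dir, paste0(stem, ".", format))
  written <- character(0)

  gwas_path <- file.path(out_dir, "gwas.tsv")
  if (file.exists(gwas_path)) {
    gw <- utils::read.table(gwas_path, header = TRUE, sep = "\t")
    # Manhattan
    f <- ext("manhattan")
    open_dev(f)
    chr_off <- c(0, cumsum(tapply(gw$pos, gw$chr, max)))
    xpos <- gw$pos + chr_off[as.integer(factor(gw$chr))]
    plot(xpos, -log10(gw$p), pch = 20, cex = 0.5,
         col = c("grey30", "steelblue")[1 + as.integer(factor(gw$chr)) %% 2],
         xlab = "genomic position", ylab = "-log10 p",
         main = "GWAS Manhattan")
    graphics::abline(h = -log10(gw_threshold), col = "red")
    graphics::abline(h = -log10(suggestive_threshold), col = "blue")
    grDevices::dev.off()
    written["manhattan"] <- f
    # QQ with lambda and 95% band
    f <- ext("qq")
    open_dev(f)
    p <- sort(gw$p)
    n <- length(p)
    exp_q <- -log10(stats::ppoints(n))
    lam <- tryCatch(genomic_inflation(gw$p), error = function(e) NA_real_)
    lo <- -log10(stats::qbeta(0.975, seq_len(n), n:1))
    hi <- -log10(stats::qbeta(0.025, seq_len(n), n:1))
    plot(exp_q, -log10(p), pch = 20, cex = 0.5,
         xlab = "expected -log10 p", ylab = "observed -log10 p",
         main = sprintf("QQ plot (lambda_GC = %.3f)", lam))
    graphics::lines(sort(exp_q, decreasing = TRUE), lo, lty = 2, col = "grey50")
    graphics::lines(sort(exp_q, decreasing = TRUE), hi, lty = 2, col = "grey50")
    graphics::abline(0, 1, col = "red")
    grDevices::dev.off()
    written["qq"] <- f
  } else warning("gwas.tsv missing: Manhattan and QQ plots skipped")

  hot_path <- file.path(out_dir, "hotspots.csv")
  if (file.exists(hot_path)) {
    H <- as.matrix(utils::read.csv(hot_path, row.names = 1))
    f <- ext("hotspots")
    open_dev(f)
    graphics::image(seq_len(nrow(H)), seq_len(ncol(H)), H,
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    xlab = "chromosome", ylab = "chromosome",
                    main = "Interaction hotspots (0.9 quantile, rescaled)")
    grDevices::dev.off()
    written["hotspots"] <- f
  } else warning("hotspots.csv missing: hotspot heatmap skipped")

  sums_path <- file.path(out_dir, "interaction_sums.tsv")
  mod_path <- file.path(out_dir, "module_assignment.tsv")
  if (file.exists(sums_path)) {
    sm <- utils::read.table(sums_path, header = TRUE, sep = "\t")
    f <- ext("pseudo_manhattan")
    open_dev(f)
    plot(seq_len(nrow(sm)), sm$sum_neglogp, pch = 20, cex = 0.6,
         xlab = "SNP (genomic order)", ylab = "sum of -log10 p",
         main = "Pseudo-Manhattan: per-SNP interaction burden")
    grDevices::dev.off()
    written["pseudo_manhattan"] <- f
  } else warning("interaction_sums.tsv missing: pseudo-Manhattan skipped")

  for (tab in c("module_stats", "replication")) {
    tp <- file.path(out_dir, paste0(tab, ".tsv"))
    if (file.exists(tp)) written[tab] <- tp
  }
  written
}
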