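#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis with its default:
#' CPM expression filter 6, LOESS span 0.75, bootstrap B = 1000,
#' differential-dispersion B = 10000, FDR threshold 0.1, variant filters
#' MAF > 0.1 and HWE p > 10^-7.5, cis window 250 kb, control matching
#' (MAF +/- 0.05, <= 100 kb, r^2 < 0.2), plus the synthetic-generator knobs
#' and a master seed from which every stage's seed is derived.
#'
#' @param ... overrides of the defaults listed above (see
#'   `pipeline_defaults()`).
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) stop("unknown config field: ", unknown[1])
  cfg[names(over)] <- over
  structure(cfg, class = "PipelineConfig")
}

#' @rdname pipeline_config
#' @export
pipeline_defaults <- function() {
  list(n_genes = 500, n_samples_per_group = 20,
       frac_diff_dispersed = 0.1, dispersion_fold_change = 5,
       cpm_threshold = 6, loess_span = 0.75,
       bootstrap_B = 1000, diffdisp_B = 10000, fdr_threshold = 0.1,
       maf_min = 0.1, hwe_p_min = 10^-7.5, cis_window = 250000,
       maf_tol = 0.05, control_max_dist = 100000, r2_max = 0.2,
       n_variants = 2000, frac_egenes = 0.1, eqtl_beta = 1,
       n_celltypes = 9, eqtl_n_perms = 99, rate_syn = 3, rate_nonsyn = 2,
       seed = 1L)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys override [pipeline_defaults()].
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_hash <- function(config) {
  tmp <- tempfile()
  writeLines(paste(deparse(unclass(config)), collapse = ""), tmp)
  h <- unname(tools::md5sum(tmp))
  unlink(tmp)
  h
}

write_stage_tsv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dispvar 0.1.0 config=%s seed=%d", hash,
                     as.integer(seed)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline stage output TSV
#'
#' @param path TSV written by [run_pipeline()] (provenance header skipped).
#' @return data.frame.
#' @export
read_stage_tsv <- function(path) {
  read.delim(path, comment.char = "#", check.names = FALSE)
}

#' Run the full synthetic-demonstration pipeline
#'
#' Simulates two-group counts with planted differentially dispersed genes,
#' filters to expressed genes, estimates per-gene dispersion in each group,
#' tests differential dispersion, computes tau from simulated pseudo-bulk
#' profiles, Pn/Ps from simulated polymorphism counts, and runs the eQTL
#' stage (genotype simulation, MAF/HWE filtering, cis scan with planted
#' effects, permutation gene-level p, control matching) on the second
#' group's samples. Every output TSV carries a provenance header (version,
#' config hash, stage seed); the run is deterministic in the master seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @param verbose print per-stage record counts.
#' @return `out_dir`, invisibly; outputs: `counts.tsv` (+ `.genes.tsv`),
#'   `dispersion_groupA.tsv`, `dispersion_groupB.tsv`, `diffdisp.tsv`,
#'   `tau.tsv`, `pnps.tsv`, `eqtl_gene_p.tsv`, `control_matches.tsv`,
#'   `truth.tsv`, `log.txt`.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  seed <- config$seed
  logf <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    logf <<- c(logf, msg)
    if (verbose) message(msg)
  }

  # --- simulate counts -----------------------------------------------------
  sim <- simulate_counts(simulation_config(
    n_genes = config$n_genes,
    n_samples_per_group = config$n_samples_per_group,
    frac_diff_dispersed = config$frac_diff_dispersed,
    dispersion_fold_change = config$dispersion_fold_change,
    seed = derive_seed(seed, "sim")))
  write_counts(sim$counts, file.path(out_dir, "counts.tsv"))
  write_stage_tsv(sim$truth, file.path(out_dir, "truth.tsv"), hash, seed)
  say("simulated ", nrow(sim$counts$counts), " genes x ",
      ncol(sim$counts$counts), " samples")

  # --- filter + per-group dispersion ---------------------------------------
  filt <- filter_expressed(sim$counts, config$cpm_threshold)
  if (nrow(filt$counts) == 0) stop("no genes retained after CPM filter")
  say("retained ", nrow(filt$counts), " genes at CPM >= ",
      config$cpm_threshold)
  cmA <- subset_group(filt, "groupA"); cmB <- subset_group(filt, "groupB")
  fitA <- loess_residual_dispersion(fit_all(cmA), span = config$loess_span)
  fitB <- loess_residual_dispersion(fit_all(cmB), span = config$loess_span)
  write_stage_tsv(fitA, file.path(out_dir, "dispersion_groupA.tsv"), hash, seed)
  write_stage_tsv(fitB, file.path(out_dir, "dispersion_groupB.tsv"), hash, seed)

  # --- differential dispersion ---------------------------------------------
  dd <- differential_dispersion_test(cmA, cmB, B = config$diffdisp_B,
                                     seed = derive_seed(seed, "dd"),
                                     span = config$loess_span)
  write_stage_tsv(dd, file.path(out_dir, "diffdisp.tsv"), hash, seed)
  say(sum(dd$q_value < config$fdr_threshold, na.rm = TRUE),
      " differentially dispersed genes at q < ", config$fdr_threshold)

  # --- tau ------------------------------------------------------------------
  ct <- simulate_celltype_profiles(nrow(filt$counts), config$n_celltypes,
                                   seed = derive_seed(seed, "tau"))
  tv <- tau_all(ct$counts)
  names(tv) <- filt$gene_ids                     # simulated profiles per gene
  write_stage_tsv(data.frame(gene_id = filt$gene_ids, tau = unname(tv),
                             true_tau = unname(ct$true_tau)),
                  file.path(out_dir, "tau.tsv"), hash, seed)

  # --- Pn/Ps ----------------------------------------------------------------
  va <- simulate_variant_annotations(nrow(filt$counts), config$rate_syn,
                                     config$rate_nonsyn,
                                     seed = derive_seed(seed, "pnps"))
  va$gene_id <- rep(filt$gene_ids, 2)
  pn <- pnps(va)
  write_stage_tsv(pn, file.path(out_dir, "pnps.tsv"), hash, seed)
  say(length(unique(pn$gene_id)), " genes with Pn/Ps in both groups")

  # --- eQTL on group B ------------------------------------------------------
  n_ind <- ncol(cmB$counts)
  geno <- simulate_genotypes(n_ind, config$n_variants,
                             ld_block_size = 5,
                             seed = derive_seed(seed, "geno"))
  rownames(geno$dosage) <- cmB$sample_ids
  geno_f <- filter_variants(geno, config$maf_min, config$hwe_p_min)
  say(ncol(geno_f$dosage), " of ", config$n_variants,
      " variants pass MAF/HWE filters")
  expr <- inverse_normal_transform(log(compute_rpkm(cmB) + 1))
  set.seed(derive_seed(seed, "plant_eqtl"))
  genes_bed <- data.frame(gene_id = cmB$gene_ids, chrom = "chr1",
                          start = sort(sample.int(10e6 - 1000,
                                                  length(cmB$gene_ids))))
  genes_bed$end <- genes_bed$start + 999
  pairs <- cis_pairs(geno_f, genes_bed, config$cis_window)
  n_eg <- round(config$frac_egenes * length(unique(pairs$gene_id)))
  planted <- data.frame(gene = character(0), variant = character(0),
                        beta = numeric(0))
  if (n_eg > 0 && nrow(pairs) > 0) {
    eg <- sample(unique(pairs$gene_id), n_eg)
    planted <- do.call(rbind, lapply(eg, function(g) {
      vs <- pairs$variant_id[pairs$gene_id == g]
      data.frame(gene = g, variant = vs[sample.int(length(vs), 1)],
                 beta = config$eqtl_beta)
    }))
    expr <- plant_eqtls(expr, geno_f, planted)
  }
  gp <- gene_level_p(expr, geno_f, covariates = NULL, pairs,
                     n_perms = config$eqtl_n_perms,
                     seed = derive_seed(seed, "eqtl"))
  gp$planted <- gp$gene_id %in% planted$gene
  write_stage_tsv(gp, file.path(out_dir, "eqtl_gene_p.tsv"), hash, seed)
  say(sum(gp$p_gene < 0.05), " eGenes at permutation p < 0.05 (",
      nrow(planted), " planted)")
  cm_tests <- planted$variant
  if (length(cm_tests) > 0) {
    ctl <- match_control_snps(cm_tests, geno_f, config$maf_tol,
                              config$control_max_dist, config$r2_max,
                              seed = derive_seed(seed, "controls"))
    write_stage_tsv(ctl, file.path(out_dir, "control_matches.tsv"), hash, seed)
    say(sum(ctl$matched), " of ", nrow(ctl), " test SNPs matched to controls")
  }

  writeLines(logf, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

#' Summarise a completed pipeline run
#'
#' Reads the stage outputs of [run_pipeline()] and emits the headline
#' counts and correlations: genes retained, differentially dispersed genes
#' at the FDR threshold, planted-recovery fractions against the truth
#' table, cross-group dispersion correlation, dispersion-tau correlation,
#' eGene counts and matched controls. Missing stage outputs are listed and
#' a partial report returned.
#'
#' @param result_dir directory written by [run_pipeline()].
#' @param fdr_threshold q-value threshold for the differential count.
#' @return list of summary quantities (also printed); `$missing` names any
#'   absent stage outputs.
#' @export
pipeline_report <- function(result_dir, fdr_threshold = 0.1) {
  want <- c(diffdisp = "diffdisp.tsv", truth = "truth.tsv", tau = "tau.tsv",
            dispA = "dispersion_groupA.tsv", dispB = "dispersion_groupB.tsv",
            pnps = "pnps.tsv", eqtl = "eqtl_gene_p.tsv")
  paths <- file.path(result_dir, want)
  names(paths) <- names(want)
  missing <- want[!file.exists(paths)]
  out <- list(missing = unname(missing))
  have <- function(k) !(want[[k]] %in% missing)
  if (have("dispA") && have("dispB")) {
    dA <- read_stage_tsv(paths["dispA"]); dB <- read_stage_tsv(paths["dispB"])
    ok <- is.finite(dA$dispersion) & is.finite(dB$dispersion)
    out$n_genes <- nrow(dA)
    out$cross_group_dispersion_r <- cor(dA$dispersion[ok], dB$dispersion[ok])
  }
  if (have("diffdisp")) {
    dd <- read_stage_tsv(paths["diffdisp"])
    out$n_diff_dispersed <- sum(dd$q_value < fdr_threshold, na.rm = TRUE)
    if (have("truth")) {
      tr <- read_stage_tsv(paths["truth"])
      j <- merge(dd, tr[, c("gene_id", "diff_dispersed")], by = "gene_id")
      hit <- j$q_value < fdr_threshold & !is.na(j$q_value)
      out$planted_recovery <- if (any(j$diff_dispersed))
        mean(hit[j$diff_dispersed]) else NA_real_
      out$false_discovery_fraction <- if (any(hit))
        mean(!j$diff_dispersed[hit]) else 0
    }
  }
  if (have("tau") && have("dispA") && have("dispB")) {
    tv <- read_stage_tsv(paths["tau"])
    mean_disp <- (dA$dispersion + dB$dispersion) / 2
    names(mean_disp) <- dA$gene_id
    ct <- correlate_dispersion_tau(mean_disp, setNames(tv$tau, tv$gene_id))
    out$dispersion_tau_r <- ct$r
  }
  if (have("pnps")) out$n_pnps_genes <-
      length(unique(read_stage_tsv(paths["pnps"])$gene_id))
  if (have("eqtl")) {
    gp <- read_stage_tsv(paths["eqtl"])
    out$n_egenes_p05 <- sum(gp$p_gene < 0.05)
    if ("planted" %in% names(gp) && any(gp$planted))
      out$eqtl_planted_recovery <- mean(gp$p_gene[gp$planted] < 0.05)
  }
  ctl_path <- file.path(result_dir, "control_matches.tsv")
  if (file.exists(ctl_path))
    out$n_matched_controls <- sum(read_stage_tsv(ctl_path)$matched)
  out
}
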