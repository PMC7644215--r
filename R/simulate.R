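#' Simulation configuration
#'
#' Parameters of the Gamma-Poisson count generator. Per gene j, relative
#' expression draws as `lambda_ij ~ Gamma(shape = phi_j, rate = phi_j/mu_j)`
#' (so `E[lambda] = mu_j`, `Var[lambda] = mu_j^2/phi_j`) and counts as
#' `x_ij ~ Poisson(x_i+ * l_j * lambda_ij)` — overdispersed counts with
#' variance `m + m^2/phi`. The baseline mean-overdispersion trend is
#' `log(phi_j) = a + b * (log(mu_j) - location)`, a monotone function of the
#' mean, so overdispersion `1/phi` depends on expression level as in real
#' bulk RNA-seq. A fraction of genes is planted as differentially dispersed
#' by multiplying `1/phi` in the second group; their means are untouched, so
#' planted genes are not differentially expressed.
#'
#' @param n_genes number of genes.
#' @param n_samples_per_group samples per group (default 39).
#' @param n_groups number of groups, labelled as species (default 2).
#' @param library_size_range target per-sample totals, drawn log-uniformly.
#' @param effective_length_range per-gene, per-group effective lengths (bp),
#'   drawn log-uniformly.
#' @param log_mean_expression location/scale (meanlog, sdlog) of the
#'   log-normal over relative expression mu. The default location puts mean
#'   counts near 100 at a 1e7 library and 1 kb length.
#' @param trend_coefficients c(intercept a, slope b) of
#'   `log(phi) = a + b*(log(mu) - meanlog)`.
#' @param frac_diff_dispersed fraction of genes planted as differentially
#'   dispersed (default 0).
#' @param dispersion_fold_change multiplicative factor applied to
#'   overdispersion 1/phi in group 2 for planted genes (default 5).
#' @param seed integer master seed; fixed seed gives byte-identical output.
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(n_genes = 500, n_samples_per_group = 39,
                              n_groups = 2,
                              library_size_range = c(1e6, 3e7),
                              effective_length_range = c(200, 10000),
                              log_mean_expression = c(meanlog = log(1e-8),
                                                      sdlog = 1.5),
                              trend_coefficients = c(intercept = log(3),
                                                     slope = 0.3),
                              frac_diff_dispersed = 0,
                              dispersion_fold_change = 5,
                              seed = 1L) {
  stopifnot(n_genes >= 1, n_samples_per_group >= 1, n_groups >= 1,
            frac_diff_dispersed >= 0, frac_diff_dispersed <= 1,
            all(library_size_range > 0), all(effective_length_range > 0),
            dispersion_fold_change > 0)
  structure(list(n_genes = as.integer(n_genes),
                 n_samples_per_group = as.integer(n_samples_per_group),
                 n_groups = as.integer(n_groups),
                 library_size_range = library_size_range,
                 effective_length_range = effective_length_range,
                 log_mean_expression = log_mean_expression,
                 trend_coefficients = trend_coefficients,
                 frac_diff_dispersed = frac_diff_dispersed,
                 dispersion_fold_change = dispersion_fold_change,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

rlogunif <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))

#' Simulate Gamma-Poisson RNA-seq counts with known truth
#'
#' Draws counts exactly from the hierarchy `lambda_ij ~ Gamma(phi_j,
#' phi_j/mu_j)`, `x_ij ~ Poisson(T_i * l_j * lambda_ij)` for each group, with
#' group-specific effective lengths. Library sizes recorded on the returned
#' [count_matrix()] are the drawn totals that enter the Poisson rates — the
#' values a whole-transcriptome column sum would estimate — so the planted
#' `mu` is the true NB parameter for the recorded offsets. The truth table
#' records every planted parameter.
#'
#' @param config a [simulation_config()].
#' @return list with `counts` (one pooled `CountMatrix`, group labels
#'   `"groupA"`, `"groupB"`, ...; use [subset_group()] for one group) and
#'   `truth` (data.frame: gene_id, mu, phi per group, diff_dispersed flag).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(derive_seed(config$seed, "counts"))
  p <- config$n_genes; n <- config$n_samples_per_group
  G <- config$n_groups
  glabels <- paste0("group", LETTERS[seq_len(G)])
  mu <- rlnorm(p, config$log_mean_expression[1], config$log_mean_expression[2])
  a <- config$trend_coefficients[1]; b <- config$trend_coefficients[2]
  phi_base <- exp(a + b * (log(mu) - config$log_mean_expression[1]))
  bad <- which(!is.finite(phi_base) | phi_base <= 0)
  if (length(bad) > 0)
    stop("non-finite overdispersion trend value at gene index ", bad[1])
  n_dd <- round(config$frac_diff_dispersed * p)
  dd <- rep(FALSE, p)
  if (n_dd > 0) dd[sample.int(p, n_dd)] <- TRUE
  phi <- matrix(phi_base, p, G)                       # per-group phi
  if (G >= 2) phi[dd, 2] <- phi_base[dd] / config$dispersion_fold_change
  colnames(phi) <- glabels

  len <- matrix(rlogunif(p * G, config$effective_length_range), p, G,
                dimnames = list(NULL, glabels))
  gene_ids <- sprintf("gene%05d", seq_len(p))
  rownames(len) <- gene_ids

  counts <- NULL; group <- character(0); sample_ids <- character(0)
  libsize <- numeric(0)
  for (g in seq_len(G)) {
    target <- rlogunif(n, config$library_size_range)
    lam <- matrix(rgamma(p * n, shape = phi[, g], rate = phi[, g] / mu), p, n)
    mean_mat <- lam * len[, g] * rep(target, each = p)
    cg <- matrix(rpois(p * n, mean_mat), p, n)
    counts <- cbind(counts, cg)
    group <- c(group, rep(glabels[g], n))
    libsize <- c(libsize, target)
    sample_ids <- c(sample_ids, sprintf("%s_s%02d", glabels[g], seq_len(n)))
  }
  rownames(counts) <- gene_ids
  colnames(counts) <- sample_ids
  # library sizes are the drawn totals that enter the Poisson rates (only a
  # whole-transcriptome column sum would estimate them; a simulated subset
  # of genes does not), so the planted mu stays the true NB parameter for
  # the recorded offsets
  cm <- count_matrix(counts, gene_ids, sample_ids, group, len,
                     library_size = libsize)
  truth <- data.frame(gene_id = gene_ids, mu = mu,
                      as.data.frame(`colnames<-`(phi, paste0("phi_", glabels))),
                      diff_dispersed = dd)
  list(counts = cm, truth = truth)
}

#' Simulate biallelic genotypes with block LD
#'
#' Haplotype model: each variant has an alt-allele frequency drawn from
#' `maf_range`; within a block of `ld_block_size` consecutive variants each
#' haplotype copies the block founder's allele with probability `copy_prob`
#' and otherwise draws independently, giving tunable within-block r^2 while
#' blocks stay independent. Dosage = sum of two haplotypes.
#'
#' @param n_individuals,n_variants dimensions.
#' @param maf_range allele-frequency interval, subset of (0, 0.5].
#' @param ld_block_size variants per LD block (1 = independent variants).
#' @param chrom_length chromosome length (bp) from which unique sorted
#'   positions are drawn.
#' @param copy_prob probability a variant's haplotype allele copies the
#'   block founder (default 0.9).
#' @param seed integer seed.
#' @return a `GenotypeMatrix`: list with `dosage` (individuals x variants,
#'   0/1/2), `variant_id`, `chrom`, `pos` (sorted, unique, 1-based), `ref`,
#'   `alt`.
#' @export
simulate_genotypes <- function(n_individuals, n_variants,
                               maf_range = c(0.1, 0.5), ld_block_size = 1,
                               chrom_length = 10e6, copy_prob = 0.9,
                               seed = 1L) {
  if (n_variants < 1) stop("n_variants must be >= 1")
  stopifnot(n_individuals >= 1, ld_block_size >= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            chrom_length >= n_variants)
  set.seed(derive_seed(seed, "genotypes"))
  freq <- runif(n_variants, maf_range[1], maf_range[2])
  block <- ((seq_len(n_variants) - 1) %/% ld_block_size) + 1
  founder_idx <- match(block, block)                 # first variant of block
  hap <- function() {
    h <- matrix(rbinom(n_individuals * n_variants, 1,
                       rep(freq, each = n_individuals)),
                n_individuals, n_variants)
    if (ld_block_size > 1) {
      copy <- matrix(rbinom(n_individuals * n_variants, 1, copy_prob) == 1,
                     n_individuals, n_variants)
      copy[, founder_idx == seq_len(n_variants)] <- FALSE
      f <- h[, founder_idx, drop = FALSE]
      h[copy] <- f[copy]
    }
    h
  }
  dosage <- hap() + hap()
  pos <- sort(sample.int(chrom_length, n_variants))
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, n_variants, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), "")
  ids <- sprintf("var%06d", seq_len(n_variants))
  colnames(dosage) <- ids
  rownames(dosage) <- sprintf("ind%04d", seq_len(n_individuals))
  structure(list(dosage = dosage, variant_id = ids,
                 chrom = rep("chr1", n_variants), pos = pos,
                 ref = unname(ref), alt = unname(alt)),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat("GenotypeMatrix:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "variants\n")
  invisible(x)
}

#' Add cis-eQTL effects to an expression matrix
#'
#' For each (gene, variant, beta) triple, adds `beta * dosage` of the variant
#' to the gene's expression across individuals; all other entries are
#' unchanged.
#'
#' @param expression gene x individual numeric matrix (rownames = gene IDs).
#' @param genotypes a [simulate_genotypes()] object whose individuals match
#'   the expression columns.
#' @param pairs data.frame with columns `gene`, `variant`, `beta`.
#' @return the modified expression matrix.
#' @export
plant_eqtls <- function(expression, genotypes, pairs) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  if (anyDuplicated(pairs[, c("gene", "variant")]))
    stop("duplicate (gene, variant) pair")
  if (!all(pairs$gene %in% rownames(expression)))
    stop("pair references unknown gene")
  if (!all(pairs$variant %in% genotypes$variant_id))
    stop("pair references unknown variant")
  for (k in seq_len(nrow(pairs))) {
    expression[pairs$gene[k], ] <- expression[pairs$gene[k], ] +
      pairs$beta[k] * genotypes$dosage[, pairs$variant[k]]
  }
  expression
}

#' Simulate pseudo-bulk cell-type expression profiles with known tau
#'
#' Genes are a mixture of three specificity classes: uniform (equal expected
#' expression in every cell type, true tau = 0), single-type (expressed in
#' exactly one cell type, tau = 1), and graded (geometric decay across a
#' random ordering of cell types, tau strictly between 0 and 1). The stored
#' true tau is [tau()] of the generating profile; the returned matrix rows
#' are proportional to the profiles (expected counts — noiseless by default
#' so the truth is exact; set `noise = "poisson"` for count noise).
#'
#' @param n_genes,n_celltypes dimensions (`n_celltypes >= 2`).
#' @param specificity_mixture fractions c(uniform, single, graded), sum 1.
#' @param decay_range range of the geometric decay rate for graded genes.
#' @param depth expected reads per cell type column.
#' @param noise `"none"` (expected counts) or `"poisson"`.
#' @param seed integer seed.
#' @return list with `counts` (genes x cell types), `true_tau`, and `class`
#'   per gene.
#' @export
simulate_celltype_profiles <- function(n_genes, n_celltypes,
                                       specificity_mixture = c(uniform = 1/3,
                                                               single = 1/3,
                                                               graded = 1/3),
                                       decay_range = c(0.3, 0.8),
                                       depth = 1e6, noise = c("none", "poisson"),
                                       seed = 1L) {
  if (n_celltypes < 2) stop("n_celltypes must be >= 2")
  if (abs(sum(specificity_mixture) - 1) > 1e-8)
    stop("specificity_mixture fractions must sum to 1")
  noise <- match.arg(noise)
  set.seed(derive_seed(seed, "celltype"))
  K <- n_celltypes
  n_each <- diff(round(cumsum(c(0, specificity_mixture)) * n_genes))
  cls <- rep(c("uniform", "single", "graded"), n_each)
  profile <- matrix(0, n_genes, K,
                    dimnames = list(sprintf("gene%05d", seq_len(n_genes)),
                                    sprintf("celltype%02d", seq_len(K))))
  for (g in seq_len(n_genes)) {
    profile[g, ] <- switch(cls[g],
      uniform = rep(1 / K, K),
      single  = { v <- numeric(K); v[sample.int(K, 1)] <- 1; v },
      graded  = { r <- runif(1, decay_range[1], decay_range[2])
                  v <- r^(seq_len(K) - 1)
                  v[sample.int(K)] / sum(v) })
  }
  true_tau <- apply(profile, 1, tau)
  abund <- rlnorm(n_genes, log(10), 1)
  counts <- profile * abund * depth / n_genes
  if (noise == "poisson")
    counts <- matrix(rpois(length(counts), counts), n_genes, K,
                     dimnames = dimnames(counts))
  list(counts = counts, true_tau = true_tau, class = cls)
}

#' Simulate per-gene synonymous / non-synonymous polymorphism counts
#'
#' Poisson counts per gene, per group, for common (MAF > 0.1) synonymous and
#' non-synonymous polymorphisms — the raw material of Pn/Ps.
#'
#' @param n_genes number of genes.
#' @param rate_syn expected synonymous count per gene (scalar or one per
#'   group).
#' @param rate_nonsyn expected non-synonymous count per gene (scalar or one
#'   per group).
#' @param groups group labels (default two species-like groups).
#' @param seed integer seed.
#' @return data.frame: gene_id, group, n_nonsyn, n_syn — both groups present
#'   for every gene.
#' @export
simulate_variant_annotations <- function(n_genes, rate_syn, rate_nonsyn,
                                         groups = c("groupA", "groupB"),
                                         seed = 1L) {
  stopifnot(all(rate_syn >= 0), all(rate_nonsyn >= 0), n_genes >= 1)
  set.seed(derive_seed(seed, "annotations"))
  G <- length(groups)
  rs <- rep(rate_syn, length.out = G)
  rn <- rep(rate_nonsyn, length.out = G)
  do.call(rbind, lapply(seq_len(G), function(g)
    data.frame(gene_id = sprintf("gene%05d", seq_len(n_genes)),
               group = groups[g],
               n_nonsyn = rpois(n_genes, rn[g]),
               n_syn = rpois(n_genes, rs[g]))))
}
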