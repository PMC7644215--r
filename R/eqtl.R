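#' Minor allele frequency from dosages
#'
#' `min(f, 1 - f)` with `f = sum(dosage) / (2n)`.
#'
#' @param dosages vector of 0/1/2 alt-allele dosages, no missing values.
#' @return MAF in \[0, 0.5\].
#' @export
maf <- function(dosages) {
  if (length(dosages) == 0) stop("no dosages")
  if (anyNA(dosages)) stop("missing dosages not supported")
  f <- sum(dosages) / (2 * length(dosages))
  min(f, 1 - f)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed allele counts, the probability
#' of `h` heterozygotes is
#' `P(h) = n! nA! na! 2^h / ((2n)! nAA! h! naa!)` over all attainable `h`
#' (same parity as the minor-allele count), and the p-value sums `P(h)` over
#' configurations no more probable than the observed one.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (hom ref, het, hom alt).
#' @return exact p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("negative genotype counts")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no individuals")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  hs <- seq(nA %% 2, min(nA, na), by = 2)
  logp <- lfactorial(n) + lfactorial(nA) + lfactorial(na) + hs * log(2) -
    lfactorial(2 * n) - lfactorial((nA - hs) / 2) - lfactorial(hs) -
    lfactorial((na - hs) / 2)
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hs)]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

#' Filter variants on MAF and Hardy-Weinberg equilibrium
#'
#' Retains variants with `maf > maf_min` and exact-HWE p-value above
#' `hwe_p_min` (rare variants and likely genotyping errors are removed).
#' Counts removed under each criterion are attached as attributes
#' `n_removed_maf` and `n_removed_hwe`.
#'
#' @param genotypes a [simulate_genotypes()]-style `GenotypeMatrix`.
#' @param maf_min MAF threshold (default 0.1, strict).
#' @param hwe_p_min HWE p-value threshold (default `10^-7.5`).
#' @return the filtered `GenotypeMatrix`.
#' @export
filter_variants <- function(genotypes, maf_min = 0.1, hwe_p_min = 10^-7.5) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  d <- genotypes$dosage
  mafs <- apply(d, 2, maf)
  hwe <- apply(d, 2, function(x)
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2)))
  pass_maf <- mafs > maf_min
  pass_hwe <- hwe > hwe_p_min
  keep <- pass_maf & pass_hwe
  if (!any(keep)) warning("no variants retained")
  out <- subset_variants(genotypes, keep)
  attr(out, "n_removed_maf") <- sum(!pass_maf)
  attr(out, "n_removed_hwe") <- sum(pass_maf & !pass_hwe)
  out
}

#' @rdname filter_variants
#' @param keep logical or integer index over variants.
#' @export
subset_variants <- function(genotypes, keep) {
  genotypes$dosage <- genotypes$dosage[, keep, drop = FALSE]
  genotypes$variant_id <- genotypes$variant_id[keep]
  genotypes$chrom <- genotypes$chrom[keep]
  genotypes$pos <- genotypes$pos[keep]
  genotypes$ref <- genotypes$ref[keep]
  genotypes$alt <- genotypes$alt[keep]
  genotypes
}

#' Enumerate cis gene-variant pairs
#'
#' A variant is cis to a gene when it lies on the same chromosome within
#' `window` bp of the gene body: `start - window <= pos <= end + window`
#' (1-based, boundaries inclusive).
#'
#' @param genotypes `GenotypeMatrix` with sorted positions per chromosome.
#' @param genes data.frame: `gene_id`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param window cis window in bp (default 250000).
#' @return data.frame: `gene_id`, `variant_id`.
#' @export
cis_pairs <- function(genotypes, genes, window = 250000) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  for (ch in unique(genotypes$chrom)) {
    if (is.unsorted(genotypes$pos[genotypes$chrom == ch]))
      stop("variant positions not sorted on ", ch)
  }
  out <- lapply(seq_len(nrow(genes)), function(i) {
    hit <- genotypes$chrom == genes$chrom[i] &
      genotypes$pos >= genes$start[i] - window &
      genotypes$pos <= genes$end[i] + window
    if (!any(hit)) return(NULL)
    data.frame(gene_id = genes$gene_id[i],
               variant_id = genotypes$variant_id[hit])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(gene_id = character(0),
                               variant_id = character(0)) else out
}

# project covariates out of rows (genes x n) or columns (n x v)
.resid_maker <- function(covariates, n) {
  W <- if (is.null(covariates)) matrix(1, n, 1)
       else cbind(intercept = rep(1, n), as.matrix(covariates))
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) stop("covariate matrix not full rank")
  list(Q = qr.Q(qrW), k = ncol(W))
}

#' Linear cis-eQTL scan
#'
#' For each gene-variant pair, ordinary least squares of normalized
#' expression on alt-allele dosage plus covariates and an intercept
#' (covariates are projected out of both sides once — Frisch-Waugh — so the
#' per-pair fit is a fast simple regression with the correct residual
#' degrees of freedom). Betas are polarized per alt-allele copy. Pairs whose
#' dosage has no residual variance (monomorphic or collinear with a
#' covariate) are flagged with NA estimates.
#'
#' @param expression gene x individual numeric matrix (rownames = gene IDs),
#'   e.g. [inverse_normal_transform()] output.
#' @param genotypes `GenotypeMatrix` over the same individuals (rows of
#'   `dosage` aligned with expression columns).
#' @param covariates individual x k numeric matrix, or NULL.
#' @param pairs data.frame `gene_id`, `variant_id` (e.g. [cis_pairs()]).
#' @return data.frame: `gene_id`, `variant_id`, `beta`, `se`, `t`,
#'   `p_nominal`, `effect_allele`, `flagged`.
#' @export
linear_eqtl_scan <- function(expression, genotypes, covariates = NULL, pairs) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  n <- ncol(expression)
  if (nrow(genotypes$dosage) != n)
    stop("expression and genotypes cover different individuals")
  rm_ <- .resid_maker(covariates, n)
  Q <- rm_$Q; k <- rm_$k
  E <- expression - (expression %*% Q) %*% t(Q)       # genes x n residuals
  G <- genotypes$dosage - Q %*% (t(Q) %*% genotypes$dosage)  # n x v
  ss_g <- colSums(G^2)
  ss_e <- rowSums(E^2)
  df <- n - k - 1
  if (df < 1) stop("not enough residual degrees of freedom")
  gi <- match(pairs$gene_id, rownames(expression))
  vi <- match(pairs$variant_id, genotypes$variant_id)
  if (anyNA(gi)) stop("pair references unknown gene")
  if (anyNA(vi)) stop("pair references unknown variant")
  cross <- vapply(seq_len(nrow(pairs)),
                  function(r) sum(E[gi[r], ] * G[, vi[r]]), 0)
  ssg <- ss_g[vi]
  flagged <- ssg < 1e-10
  beta <- ifelse(flagged, NA_real_, cross / ssg)
  rss <- pmax(ss_e[gi] - beta^2 * ssg, 0)
  se <- sqrt(rss / df / ssg)
  se[flagged] <- NA_real_
  tstat <- beta / se            # exact fits: se = 0, t = Inf, p = 0
  p <- 2 * pt(-abs(tstat), df)
  data.frame(gene_id = pairs$gene_id, variant_id = pairs$variant_id,
             beta = beta, se = se, t = tstat, p_nominal = p,
             effect_allele = genotypes$alt[vi], flagged = flagged)
}

#' Jointly permute expression and covariates against genotypes
#'
#' One shared random permutation reassigns the sample labels of the
#' expression columns and covariate rows while genotypes stay fixed — the
#' permutation null for eQTL scanning. Expression-covariate alignment is
#' preserved.
#'
#' @param expression gene x individual matrix.
#' @param covariates individual x k matrix or NULL.
#' @param seed integer seed.
#' @return list: `expression`, `covariates`, `permutation`.
#' @export
permute_samples <- function(expression, covariates = NULL, seed = 1L) {
  set.seed(derive_seed(seed, "permute"))
  perm <- sample.int(ncol(expression))
  list(expression = expression[, perm, drop = FALSE],
       covariates = if (is.null(covariates)) NULL
                    else covariates[perm, , drop = FALSE],
       permutation = perm)
}

#' Gene-level eQTL significance by min-p permutation
#'
#' Tests whether a gene contains any eQTL: the observed statistic is the
#' minimum nominal p over the gene's cis pairs, compared with the same
#' minimum under `n_perms` joint sample permutations (Westfall-Young style,
#' which accounts for the number and linkage of the gene's variants).
#' `p_gene = (1 + #{perm min-p <= observed}) / (n_perms + 1)`.
#'
#' @inheritParams linear_eqtl_scan
#' @param n_perms number of permutations (>= 19).
#' @param seed integer seed.
#' @return data.frame: `gene_id`, `min_p_nominal`, `p_gene`, `n_pairs`.
#'   Genes with no unflagged pair are absent.
#' @export
gene_level_p <- function(expression, genotypes, covariates = NULL, pairs,
                         n_perms = 99, seed = 1L) {
  if (n_perms < 19) stop("n_perms must be >= 19")
  obs <- linear_eqtl_scan(expression, genotypes, covariates, pairs)
  obs <- obs[!obs$flagged & !is.na(obs$p_nominal), ]
  if (nrow(obs) == 0) stop("no testable pairs")
  obs_min <- tapply(obs$p_nominal, obs$gene_id, min)
  exceed <- setNames(integer(length(obs_min)), names(obs_min))
  for (b in seq_len(n_perms)) {
    pm <- permute_samples(expression, covariates,
                          seed = derive_seed(seed, paste0("geneperm", b)))
    sc <- linear_eqtl_scan(pm$expression, genotypes, pm$covariates, pairs)
    sc <- sc[!sc$flagged & !is.na(sc$p_nominal), ]
    pm_min <- tapply(sc$p_nominal, sc$gene_id, min)
    common <- intersect(names(exceed), names(pm_min))
    exceed[common] <- exceed[common] + (pm_min[common] <= obs_min[common])
  }
  data.frame(gene_id = names(obs_min),
             min_p_nominal = as.numeric(obs_min),
             p_gene = as.numeric((1 + exceed) / (n_perms + 1)),
             n_pairs = as.integer(table(obs$gene_id)[names(obs_min)]),
             row.names = NULL)
}

#' Linkage disequilibrium r-squared between two variants
#'
#' Squared Pearson correlation of dosage vectors over the same individuals.
#'
#' @param d1,d2 dosage vectors.
#' @return r^2 in \[0, 1\]; NA (with a warning) if either is monomorphic.
#' @export
ld_r2 <- function(d1, d2) {
  if (length(d1) != length(d2)) stop("dosage vectors differ in length")
  if (sd(d1) == 0 || sd(d2) == 0) {
    warning("monomorphic variant: r2 undefined")
    return(NA_real_)
  }
  cor(d1, d2)^2
}

#' Match control SNPs to test SNPs
#'
#' For every test SNP, draws one control uniformly at random (seeded) among
#' candidate variants with matching allele frequency (absolute MAF
#' difference <= `maf_tol`), within `max_dist` bp on the same chromosome,
#' and unlinked to the test SNP (`r^2 < r2_max`). Test SNPs themselves are
#' never candidates; tests with no eligible candidate are flagged, not
#' dropped. Every emitted match is re-checked against all three constraints.
#'
#' @param tests character vector of test variant IDs (present in
#'   `candidates`).
#' @param candidates `GenotypeMatrix` holding both test and candidate
#'   variants.
#' @param maf_tol absolute MAF tolerance (default 0.05).
#' @param max_dist maximum distance in bp (default 100000).
#' @param r2_max LD exclusion threshold (default 0.2).
#' @param seed integer seed.
#' @return data.frame: `test_variant`, `control_variant` (NA when
#'   unmatched), `maf_diff`, `distance`, `r2`, `matched`.
#' @export
match_control_snps <- function(tests, candidates, maf_tol = 0.05,
                               max_dist = 100000, r2_max = 0.2, seed = 1L) {
  stopifnot(inherits(candidates, "GenotypeMatrix"))
  ti <- match(tests, candidates$variant_id)
  if (anyNA(ti)) stop("unknown test variant: ", tests[which(is.na(ti))[1]])
  set.seed(derive_seed(seed, "controls"))
  mafs <- apply(candidates$dosage, 2, maf)
  res <- lapply(seq_along(tests), function(r) {
    i <- ti[r]
    ok <- which(candidates$chrom == candidates$chrom[i] &
                abs(candidates$pos - candidates$pos[i]) <= max_dist &
                abs(mafs - mafs[i]) <= maf_tol &
                !(candidates$variant_id %in% tests))
    ok <- ok[vapply(ok, function(j) {
      r2 <- suppressWarnings(ld_r2(candidates$dosage[, i],
                                   candidates$dosage[, j]))
      isTRUE(r2 < r2_max)
    }, TRUE)]
    if (length(ok) == 0)
      return(data.frame(test_variant = tests[r],
                        control_variant = NA_character_,
                        maf_diff = NA_real_, distance = NA_real_,
                        r2 = NA_real_, matched = FALSE))
    j <- ok[sample.int(length(ok), 1)]
    data.frame(test_variant = tests[r],
               control_variant = candidates$variant_id[j],
               maf_diff = mafs[j] - mafs[i],
               distance = abs(candidates$pos[j] - candidates$pos[i]),
               r2 = ld_r2(candidates$dosage[, i], candidates$dosage[, j]),
               matched = TRUE)
  })
  out <- do.call(rbind, res)
  m <- out[out$matched, ]
  stopifnot(all(abs(m$maf_diff) <= maf_tol), all(m$distance <= max_dist),
            all(m$r2 < r2_max))
  out
}

#' Align effect sizes from two datasets to the same allele
#'
#' eQTL software may polarize betas by minor or by reference allele, which
#' can differ between datasets; when the two effect alleles are swapped the
#' second beta is negated. Allele sets that do not match (including
#' strand-ambiguous mismatches like A/G vs C/T) raise an error — the pair
#' must be excluded rather than guessed.
#'
#' @param beta_A,beta_B effect sizes.
#' @param alleles_A,alleles_B length-2 character vectors `(effect, other)`.
#' @return list: `beta_A`, `beta_B` (aligned to dataset A's effect allele),
#'   `flipped`.
#' @export
repolarize_effects <- function(beta_A, alleles_A, beta_B, alleles_B) {
  if (!setequal(alleles_A, alleles_B) || length(alleles_A) != 2 ||
      length(alleles_B) != 2 || alleles_A[1] == alleles_A[2])
    stop("allele sets differ; pair must be excluded")
  if (alleles_A[1] == alleles_B[1]) {
    list(beta_A = beta_A, beta_B = beta_B, flipped = FALSE)
  } else {
    list(beta_A = beta_A, beta_B = -beta_B, flipped = TRUE)
  }
}

#' Hypergeometric eGene overlap test
#'
#' 2x2 enrichment of two gene sets drawn from a common universe: upper-tail
#' hypergeometric p-value `P(overlap >= observed)` and the odds ratio (with
#' a Haldane 0.5 correction when any cell is empty — the uncorrected OR is
#' also returned).
#'
#' @param set_A,set_B character gene sets, subsets of `universe`.
#' @param universe character universe of tested genes.
#' @return list: `overlap`, `odds_ratio`, `odds_ratio_raw`, `p`.
#' @export
egene_overlap_test <- function(set_A, set_B, universe) {
  if (length(universe) == 0) stop("empty universe")
  if (!all(set_A %in% universe) || !all(set_B %in% universe))
    stop("sets must be subsets of the universe")
  set_A <- unique(set_A); set_B <- unique(set_B); universe <- unique(universe)
  a <- length(intersect(set_A, set_B))
  b <- length(set_A) - a
  c_ <- length(set_B) - a
  d <- length(universe) - length(set_A) - length(set_B) + a
  or_raw <- (a * d) / (b * c_)
  or <- if (any(c(a, b, c_, d) == 0))
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5)) else or_raw
  p <- phyper(a - 1, length(set_A), length(universe) - length(set_A),
              length(set_B), lower.tail = FALSE)
  list(overlap = a, odds_ratio = or, odds_ratio_raw = or_raw, p = p)
}

#' Compare two p-value sets (QQ comparison)
#'
#' One-sided Mann-Whitney test of whether the test set's p-values are
#' stochastically smaller than the control set's, plus sorted -log10
#' quantile pairs for QQ plotting.
#'
#' @param p_test,p_control p-value vectors.
#' @param alternative only `"test smaller"` is meaningful here.
#' @return list: `p` (Mann-Whitney, one-sided), `U`, `qq` (data.frame with
#'   `neglog10_test`, `neglog10_control` at matched quantiles).
#' @export
qq_compare <- function(p_test, p_control, alternative = "test smaller") {
  if (length(p_test) == 0 || length(p_control) == 0)
    stop("both p-value sets must be non-empty")
  res <- group_difference_test(c(p_test, p_control),
                               c(rep(TRUE, length(p_test)),
                                 rep(FALSE, length(p_control))),
                               alternative = "less")
  m <- min(length(p_test), length(p_control))
  probs <- (seq_len(m) - 0.5) / m
  qq <- data.frame(
    neglog10_test = -log10(quantile(p_test, probs, names = FALSE)),
    neglog10_control = -log10(quantile(p_control, probs, names = FALSE)))
  list(p = res$p, U = res$U, qq = qq)
}
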