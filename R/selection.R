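#' Pn/Ps polymorphism constraint ratio
#'
#' Per-gene, per-group ratio of common non-synonymous to synonymous
#' polymorphisms — the within-species analogue of dN/dS. Genes with no
#' polymorphism at all (`Pn + Ps = 0`) in either group are removed, then a
#' pseudocount of 0.5 is added to both counts:
#' `ratio = (Pn + 0.5) / (Ps + 0.5)`.
#'
#' @param table data.frame with columns `gene_id`, `group`, `n_nonsyn`,
#'   `n_syn`; every retained gene must have a row for each group.
#' @return data.frame: `gene_id`, `group`, `n_nonsyn`, `n_syn`, `pnps`.
#' @export
pnps <- function(table) {
  req <- c("gene_id", "group", "n_nonsyn", "n_syn")
  if (!all(req %in% names(table))) stop("missing required columns")
  if (any(table$n_nonsyn < 0 | table$n_syn < 0)) stop("negative counts")
  groups <- unique(table$group)
  counts_per_gene <- table(table$gene_id)
  incomplete <- names(counts_per_gene)[counts_per_gene < length(groups)]
  if (length(incomplete) > 0)
    stop("missing group row for gene ", incomplete[1])
  tot <- table$n_nonsyn + table$n_syn
  zero_genes <- unique(table$gene_id[tot == 0])
  out <- table[!(table$gene_id %in% zero_genes), , drop = FALSE]
  out$pnps <- (out$n_nonsyn + 0.5) / (out$n_syn + 0.5)
  rownames(out) <- NULL
  out
}

#' Between-group Pn/Ps ratio
#'
#' Elementwise `pnps_B / pnps_A` per gene; strictly positive by pseudocount
#' construction, and its log is antisymmetric under swapping the groups.
#'
#' @param pnps_A,pnps_B named per-gene Pn/Ps vectors (names = gene IDs).
#' @return named vector of ratios over the shared genes.
#' @export
interspecies_pnps_ratio <- function(pnps_A, pnps_B) {
  shared <- intersect(names(pnps_A), names(pnps_B))
  if (length(shared) == 0) stop("no shared genes")
  setNames(pnps_B[shared] / pnps_A[shared], shared)
}

#' Mann-Whitney comparison of a score between two gene groups
#'
#' Rank-sum test of `scores[group_mask]` vs `scores[!group_mask]`: exact
#' when both groups are small and tie-free, tie-corrected normal
#' approximation otherwise (via [stats::wilcox.test()]).
#'
#' @param scores numeric vector.
#' @param group_mask logical vector: TRUE = first group.
#' @param alternative `"two.sided"`, `"greater"` (first group larger) or
#'   `"less"`.
#' @return list: `U` statistic (first group), `p`.
#' @export
group_difference_test <- function(scores, group_mask,
                                  alternative = c("two.sided", "greater",
                                                  "less")) {
  alternative <- match.arg(alternative)
  x <- scores[group_mask]; y <- scores[!group_mask]
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  wt <- suppressWarnings(wilcox.test(x, y, alternative = alternative,
                                     exact = length(x) <= 8 && length(y) <= 8))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Spearman correlation across quantile bins
#'
#' Bins genes into `n_bins` equal-size quantile groups by `scores_x` and
#' correlates the bin index with the per-bin median of `scores_y` (Spearman).
#' The plain gene-level Spearman correlation is always reported alongside —
#' the binned version summarises the monotone trend across the full range
#' rather than only the extremes.
#'
#' @param scores_x,scores_y numeric vectors of equal length.
#' @param n_bins number of quantile bins (>= 3, default 10).
#' @return list: `rho`, `p` (binned), `rho_genewise`, `p_genewise`.
#' @export
quantile_spearman <- function(scores_x, scores_y, n_bins = 10) {
  if (n_bins < 3) stop("n_bins must be >= 3")
  n <- length(scores_x)
  if (n < n_bins) stop("need >= n_bins observations")
  ord <- order(scores_x, seq_len(n))           # stable tie-break
  bin <- integer(n); bin[ord] <- ceiling(seq_len(n) * n_bins / n)
  med <- tapply(scores_y, bin, median)
  ct <- suppressWarnings(cor.test(as.numeric(names(med)), as.numeric(med),
                                  method = "spearman"))
  ctg <- suppressWarnings(cor.test(scores_x, scores_y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value,
       rho_genewise = unname(ctg$estimate), p_genewise = ctg$p.value)
}

#' Extract top- and bottom-decile score groups
#'
#' Partitions genes into deciles of `scores_x` (ties broken by stable input
#' order) and returns the `scores_y` values of the bottom and top deciles,
#' each of size `floor(n/10)` — e.g. for ECDF plotting or
#' [group_difference_test()].
#'
#' @param scores_x ranking variable.
#' @param scores_y values to extract.
#' @return list: `bottom`, `top` (numeric vectors), `bottom_idx`, `top_idx`.
#' @export
decile_ecdf_extract <- function(scores_x, scores_y) {
  n <- length(scores_x)
  if (n < 20) stop("need >= 20 genes")
  k <- floor(n / 10)
  ord <- order(scores_x, seq_len(n))
  bottom_idx <- ord[seq_len(k)]
  top_idx <- ord[seq(n - k + 1, n)]
  list(bottom = scores_y[bottom_idx], top = scores_y[top_idx],
       bottom_idx = bottom_idx, top_idx = top_idx)
}
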