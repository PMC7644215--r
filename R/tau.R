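#' Pseudo-bulk expression by cell type
#'
#' Sums raw single-cell counts within each cell-type label and converts each
#' cell-type column to counts per million, the input scale for [tau()].
#'
#' @param sc_counts cell x gene count matrix.
#' @param cell_labels cell-type label per cell (row); no NAs.
#' @return genes x cell-types CPM matrix of class `PseudoBulkMatrix`.
#' @export
pseudobulk <- function(sc_counts, cell_labels) {
  sc_counts <- as.matrix(sc_counts)
  if (length(cell_labels) != nrow(sc_counts))
    stop("one label per cell (row) required")
  if (anyNA(cell_labels)) stop("unlabeled cell at row ",
                               which(is.na(cell_labels))[1])
  types <- sort(unique(as.character(cell_labels)))
  pb <- vapply(types, function(k)
    colSums(sc_counts[cell_labels == k, , drop = FALSE]),
    numeric(ncol(sc_counts)))
  cpm <- sweep(pb, 2, colSums(pb), "/") * 1e6
  structure(cpm, class = c("PseudoBulkMatrix", "matrix"))
}

#' Tau cell-type-specificity index
#'
#' For a gene's non-negative expression across K >= 2 cell types:
#' `tau = sum_k (1 - x_k / max(x)) / (K - 1)`, ranging from 0 (equally
#' expressed in all cell types) to 1 (exclusive to a single cell type).
#' Scale-invariant; undefined (NA) for an all-zero gene.
#'
#' @param expression_row non-negative vector of length K >= 2.
#' @return tau in \[0, 1\], or NA when the gene is unexpressed.
#' @export
tau <- function(expression_row) {
  if (length(expression_row) < 2) stop("tau needs K >= 2 cell types")
  if (any(expression_row < 0)) stop("negative expression value")
  mx <- max(expression_row)
  if (mx == 0) return(NA_real_)
  sum(1 - expression_row / mx) / (length(expression_row) - 1)
}

#' Tau for every gene of a pseudo-bulk matrix
#'
#' @param pb genes x cell-types matrix (e.g. [pseudobulk()] output).
#' @return named numeric vector of tau values.
#' @export
tau_all <- function(pb) {
  if (ncol(pb) < 2) stop("tau needs K >= 2 cell types")
  apply(unclass(pb), 1, tau)
}

#' Correlation between dispersion and cell-type-specificity
#'
#' Inner-joins the two per-gene vectors by name and reports the Pearson
#' correlation and its two-sided p-value.
#'
#' @param dispersion named per-gene dispersion vector.
#' @param tau_values named per-gene tau vector.
#' @return list: `r`, `p`, `n_genes` (join size).
#' @export
correlate_dispersion_tau <- function(dispersion, tau_values) {
  shared <- intersect(names(dispersion), names(tau_values))
  x <- dispersion[shared]; y <- tau_values[shared]
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < 3) stop("fewer than 3 shared genes after join")
  ct <- cor.test(x[keep], y[keep], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_genes = sum(keep))
}
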