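#' Construct a CountMatrix
#'
#' Container for a genes x samples integer RNA-seq count matrix together with
#' the metadata the Gamma-Poisson model needs: a group (species) label per
#' sample, the library size `x_i+` per sample (total reads, fixed at
#' construction as the column sum), and the effective length `l_j` per gene
#' and group — the length of the orthologous exonic region over which the
#' gene's reads were counted, which may differ between species.
#'
#' @param counts integer matrix, genes x samples, non-negative.
#' @param gene_ids character vector of unique gene IDs (default: rownames).
#' @param sample_ids character vector of unique sample IDs (default: colnames).
#' @param group character/factor of length `ncol(counts)`: species or
#'   population label per sample.
#' @param effective_length numeric matrix (genes x groups, column names =
#'   group levels) or vector (recycled across groups) of effective lengths in
#'   bp; all > 0.
#' @param library_size optional per-sample totals; defaults to column sums
#'   and is frozen thereafter (gene filtering does not recompute it).
#' @return An object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         sample_ids = colnames(counts), group,
                         effective_length, library_size = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(ncol(counts)))
  if (anyDuplicated(gene_ids)) stop("duplicate gene IDs")
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs")
  if (length(group) != ncol(counts)) stop("one group label per sample required")
  group <- as.character(group)
  groups <- unique(group)
  if (is.null(dim(effective_length))) {
    effective_length <- matrix(
      rep(effective_length, length.out = nrow(counts) * length(groups)),
      nrow(counts), length(groups), dimnames = list(gene_ids, groups))
  }
  effective_length <- as.matrix(effective_length)
  if (nrow(effective_length) != nrow(counts))
    stop("effective_length must have one row per gene")
  if (is.null(colnames(effective_length)))
    colnames(effective_length) <- groups
  if (!all(groups %in% colnames(effective_length)))
    stop("effective_length missing a column for some group")
  if (any(effective_length <= 0)) stop("effective lengths must be > 0")
  rownames(counts) <- gene_ids
  colnames(counts) <- sample_ids
  rownames(effective_length) <- gene_ids
  structure(list(counts = counts, gene_ids = gene_ids,
                 sample_ids = sample_ids, group = group,
                 library_size = setNames(as.numeric(library_size), sample_ids),
                 effective_length = effective_length),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples;",
      "groups:", paste(unique(x$group), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Counts per million
#'
#' CPM_ij = 1e6 * x_ij / x_i+, using the library sizes frozen at
#' construction (so columns sum to 1e6 only before gene filtering).
#'
#' @param x a [count_matrix()].
#' @return numeric matrix, genes x samples.
#' @export
compute_cpm <- function(x) {
  stopifnot(inherits(x, "CountMatrix"))
  bad <- x$library_size <= 0
  if (any(bad))
    stop("zero library size for sample(s): ",
         paste(x$sample_ids[bad], collapse = ", "))
  sweep(x$counts, 2, x$library_size, "/") * 1e6
}

#' Reads per kilobase per million
#'
#' RPKM_ij = CPM_ij / (l_j / 1000) with the effective length of the sample's
#' own group, so orthologous regions of different length between species are
#' put on a common scale.
#'
#' @inheritParams compute_cpm
#' @return numeric matrix, genes x samples.
#' @export
compute_rpkm <- function(x) {
  cpm <- compute_cpm(x)
  len <- x$effective_length[, x$group, drop = FALSE]  # genes x samples
  cpm / (len / 1000)
}

#' Filter to expressed genes
#'
#' Excludes genes whose CPM is below `cpm_threshold` in every sample (pooled
#' across groups by default): a gene is retained iff it reaches the threshold
#' in at least one sample. Library sizes are not recomputed after filtering.
#'
#' @inheritParams compute_cpm
#' @param cpm_threshold minimum CPM a gene must reach in >= 1 sample
#'   (default 6).
#' @param per_group if TRUE, a gene is retained when it passes the rule
#'   within any single group's samples considered alone.
#' @return the filtered `CountMatrix`.
#' @export
filter_expressed <- function(x, cpm_threshold = 6, per_group = FALSE) {
  stopifnot(cpm_threshold > 0)
  cpm <- compute_cpm(x)
  if (per_group) {
    keep <- Reduce(`|`, lapply(unique(x$group), function(g)
      apply(cpm[, x$group == g, drop = FALSE] >= cpm_threshold, 1, any)))
  } else {
    keep <- apply(cpm >= cpm_threshold, 1, any)
  }
  if (!any(keep)) warning("no genes retained at CPM threshold ", cpm_threshold)
  x$counts <- x$counts[keep, , drop = FALSE]
  x$gene_ids <- x$gene_ids[keep]
  x$effective_length <- x$effective_length[keep, , drop = FALSE]
  x
}

#' Rank-based inverse normal transform
#'
#' Quantile-normalises each row to a standard normal: values are replaced by
#' `qnorm((rank - 0.5)/n)` with average ranks for ties. Rank order within a
#' row is preserved; constant rows become all zeros and are flagged via the
#' `"constant_rows"` attribute.
#'
#' @param m numeric matrix with >= 3 columns.
#' @return transformed matrix with attribute `constant_rows`.
#' @export
inverse_normal_transform <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 3) stop("need >= 3 samples")
  n <- ncol(m)
  constant <- apply(m, 1, function(r) diff(range(r)) == 0)
  out <- t(apply(m, 1, function(r) qnorm((rank(r) - 0.5) / n)))
  out[constant, ] <- 0
  dimnames(out) <- dimnames(m)
  attr(out, "constant_rows") <- which(constant)
  out
}

#' Write / read a CountMatrix as TSV
#'
#' `write_counts()` writes two files: `<path>` with the counts (gene IDs in
#' column 1, header `gene_id` then sample IDs, a comment line carrying group
#' labels and library sizes) and `<path>` with `.genes.tsv` appended holding
#' gene metadata (gene_id and one effective-length column per group).
#' `read_counts()` reverses it losslessly for integer counts.
#'
#' @param x a [count_matrix()].
#' @param path output TSV path for the counts.
#' @return `read_counts()` returns a `CountMatrix`; `write_counts()` returns
#'   `path` invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "CountMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# group\t", paste(x$group, collapse = "\t")), con)
  writeLines(paste0("# library_size\t",
                    paste(format(x$library_size, scientific = FALSE,
                                 trim = TRUE, digits = 15), collapse = "\t")),
             con)
  df <- data.frame(gene_id = x$gene_ids, x$counts, check.names = FALSE)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  meta <- data.frame(gene_id = x$gene_ids, x$effective_length,
                     check.names = FALSE)
  names(meta)[-1] <- paste0("effective_length_",
                            colnames(x$effective_length))
  write.table(meta, paste0(path, ".genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  lines <- readLines(path, n = 2)
  if (!startsWith(lines[1], "# group") || !startsWith(lines[2], "# library_size"))
    stop("malformed header in ", path, " (line 1-2)")
  group <- strsplit(lines[1], "\t")[[1]][-1]
  libsize <- as.numeric(strsplit(lines[2], "\t")[[1]][-1])
  df <- read.delim(path, skip = 2, check.names = FALSE)
  if (names(df)[1] != "gene_id") stop("malformed header: line 3 must start gene_id")
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene ID at line ",
         3 + which(duplicated(df$gene_id))[1])
  counts <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative or non-integer count at line ", 3 + bad[1, 1])
  rownames(counts) <- df$gene_id
  meta <- read.delim(paste0(path, ".genes.tsv"), check.names = FALSE)
  el <- as.matrix(meta[, -1, drop = FALSE])
  colnames(el) <- sub("^effective_length_", "", colnames(el))
  count_matrix(counts, gene_ids = df$gene_id, sample_ids = colnames(counts),
               group = group, effective_length = el, library_size = libsize)
}

#' Subset a CountMatrix to one group's samples
#'
#' Library sizes stay frozen; effective lengths keep all group columns.
#' @param x a [count_matrix()].
#' @param group group label to keep.
#' @return a `CountMatrix` with only that group's columns.
#' @export
subset_group <- function(x, group) {
  stopifnot(inherits(x, "CountMatrix"), group %in% x$group)
  keep <- x$group == group
  x$counts <- x$counts[, keep, drop = FALSE]
  x$sample_ids <- x$sample_ids[keep]
  x$library_size <- x$library_size[keep]
  x$group <- x$group[keep]
  x
}
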