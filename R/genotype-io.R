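#' Write / read genotypes as minimal VCF v4.2
#'
#' Biallelic SNPs with a GT-only FORMAT. The reader accepts exactly this
#' subset: single-base REF/ALT, one ALT allele, diploid unphased or phased
#' GT, no missing genotypes (a `.` genotype is rejected with the offending
#' line).
#'
#' @param genotypes a `GenotypeMatrix`.
#' @param path file path.
#' @return `read_vcf()` returns a `GenotypeMatrix`; `write_vcf()` returns
#'   `path` invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  gt <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(genotypes$dosage)),
                     collapse = "\t")), con)
  for (v in seq_along(genotypes$variant_id)) {
    writeLines(paste(c(genotypes$chrom[v], genotypes$pos[v],
                       genotypes$variant_id[v], genotypes$ref[v],
                       genotypes$alt[v], ".", "PASS", ".", "GT",
                       gt[genotypes$dosage[, v] + 1]), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1) stop("missing #CHROM header line")
  cols <- strsplit(lines[hdr], "\t")[[1]]
  inds <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  n_v <- length(body)
  dosage <- matrix(NA_integer_, length(inds), n_v,
                   dimnames = list(inds, NULL))
  chrom <- pos <- id <- ref <- alt <- vector("character", n_v)
  for (v in seq_len(n_v)) {
    f <- strsplit(body[v], "\t")[[1]]
    if (grepl(",", f[5])) stop("multi-allelic record at line ", hdr + v)
    if (nchar(f[4]) != 1 || nchar(f[5]) != 1)
      stop("non-SNP record at line ", hdr + v)
    if (!startsWith(f[9], "GT")) stop("FORMAT without leading GT at line ",
                                      hdr + v)
    gts <- sub(":.*", "", f[-(1:9)])
    if (any(grepl("\\.", gts))) stop("missing genotype at line ", hdr + v)
    dosage[, v] <- vapply(strsplit(gts, "[/|]"),
                          function(a) sum(as.integer(a)), 0L)
    chrom[v] <- f[1]; pos[v] <- f[2]; id[v] <- f[3]
    ref[v] <- f[4]; alt[v] <- f[5]
  }
  colnames(dosage) <- id
  structure(list(dosage = dosage, variant_id = id, chrom = chrom,
                 pos = as.integer(pos), ref = ref, alt = alt),
            class = "GenotypeMatrix")
}

#' Write / read genotypes as dosage TSV
#'
#' Long header block of variant metadata followed by an individuals x
#' variants dosage table; lossless round-trip.
#'
#' @inheritParams write_vcf
#' @export
write_dosage <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  meta <- data.frame(variant_id = genotypes$variant_id,
                     chrom = genotypes$chrom, pos = genotypes$pos,
                     ref = genotypes$ref, alt = genotypes$alt)
  write.table(meta, paste0(path, ".variants.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  df <- data.frame(individual = rownames(genotypes$dosage),
                   genotypes$dosage, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage
#' @export
read_dosage <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  meta <- read.delim(paste0(path, ".variants.tsv"), check.names = FALSE)
  dosage <- as.matrix(df[, -1, drop = FALSE])
  rownames(dosage) <- df$individual
  if (any(!dosage %in% 0:2)) stop("dosages must be 0/1/2")
  structure(list(dosage = dosage, variant_id = meta$variant_id,
                 chrom = as.character(meta$chrom), pos = meta$pos,
                 ref = meta$ref, alt = meta$alt),
            class = "GenotypeMatrix")
}
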