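test_that("MAF counts alleles correctly", {
  expect_equal(maf(c(0, 0, 0, 0)), 0)
  expect_equal(maf(c(1, 1, 1, 1)), 0.5)
  expect_equal(maf(c(0, 1, 2, 2)), 0.375)
  expect_error(maf(numeric(0)), "no dosages")
})

test_that("HWE exact test matches hand enumeration and the oracle", {
  expect_equal(hwe_exact_test(10, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 2, 0), 1)
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)
  expect_error(hwe_exact_test(-1, 2, 0), "negative")
  set.seed(77)
  for (i in 1:40) {
    n <- sample(2:25, 1)
    g <- as.vector(rmultinom(1, n, c(0.35, 0.4, 0.25)))
    expect_equal(hwe_exact_test(g[1], g[2], g[3]),
                 hwe_enum_oracle(g[1], g[2], g[3]), tolerance = 1e-10)
  }
})

test_that("variant filters apply the MAF and HWE thresholds", {
  d <- cbind(rep(c(0L, 1L), c(36, 4)),              # MAF 0.05 -> out
             rep(c(0L, 1L, 2L), c(10, 20, 10)),     # (10,20,10): HWE-perfect
             rep(c(0L, 2L), c(20, 20)))             # no hets: HWE violation
  g <- manual_genotypes(d)
  f <- filter_variants(g, maf_min = 0.1, hwe_p_min = 10^-7.5)
  expect_identical(f$variant_id, "v2")
  expect_equal(attr(f, "n_removed_maf"), 1L + 0L)
  expect_equal(attr(f, "n_removed_hwe"), 1L)
  # permissive thresholds pass every polymorphic variant
  f0 <- filter_variants(g, maf_min = 0, hwe_p_min = 0)
  expect_identical(f0$variant_id, g$variant_id)
})

test_that("cis pairing respects the inclusive window boundary", {
  g <- manual_genotypes(matrix(0L, 4, 3),
                        pos = c(750000, 750001, 1200000))
  genes <- data.frame(gene_id = "gA", chrom = "chr1",
                      start = 1000000, end = 1100000)
  pr <- cis_pairs(g, genes, window = 250000)
  # start - 250000 = 750000 included; 749999... v1 at exactly the boundary
  expect_setequal(pr$variant_id, c("v1", "v2", "v3"))
  pr2 <- cis_pairs(g, genes, window = 249999)
  expect_setequal(pr2$variant_id, c("v2", "v3"))
  gu <- manual_genotypes(matrix(0L, 4, 2), pos = c(500, 100))
  expect_error(cis_pairs(gu, genes), "sorted")
})

test_that("the eQTL scan recovers a noiseless planted effect exactly", {
  set.seed(8)
  g <- simulate_genotypes(30, 10, seed = 4)
  expr <- matrix(0, 2, 30, dimnames = list(c("gA", "gB"), NULL))
  expr["gA", ] <- 1 * g$dosage[, 3]
  pairs <- data.frame(gene_id = c("gA", "gB"),
                      variant_id = g$variant_id[c(3, 5)])
  sc <- linear_eqtl_scan(expr, g, NULL, pairs)
  expect_equal(sc$beta[1], 1, tolerance = 1e-10)
  expect_lt(sc$p_nominal[1], 1e-20)
  expect_identical(sc$effect_allele, g$alt[c(3, 5)])
  # collinear covariate: dosage has no residual variance -> flagged
  sc2 <- linear_eqtl_scan(expr, g, cbind(g$dosage[, 3]), pairs[1, ])
  expect_true(sc2$flagged[1])
  expect_true(is.na(sc2$beta[1]))
})

test_that("null scan p-values are uniform", {
  set.seed(9)
  g <- simulate_genotypes(60, 100, seed = 10)
  expr <- matrix(rnorm(50 * 60), 50, 60,
                 dimnames = list(paste0("g", 1:50), NULL))
  pairs <- expand.grid(gene_id = paste0("g", 1:50),
                       variant_id = g$variant_id,
                       stringsAsFactors = FALSE)
  sc <- linear_eqtl_scan(expr, g, NULL, pairs)
  ks <- suppressWarnings(ks.test(sc$p_nominal, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("joint sample permutation destroys signal but keeps alignment", {
  set.seed(10)
  g <- simulate_genotypes(40, 30, seed = 11)
  expr <- matrix(rnorm(20 * 40), 20, 40,
                 dimnames = list(paste0("g", 1:20), rownames(g$dosage)))
  cov <- matrix(rnorm(40), 40, 1, dimnames = list(rownames(g$dosage), "pc1"))
  planted <- data.frame(gene = paste0("g", 1:20),
                        variant = g$variant_id[seq_len(20)], beta = 1.5)
  expr <- plant_eqtls(expr, g, planted)
  pairs <- data.frame(gene_id = planted$gene, variant_id = planted$variant)
  p_obs <- linear_eqtl_scan(expr, g, cov, pairs)$p_nominal
  pm <- permute_samples(expr, cov, seed = 12)
  expect_identical(colnames(pm$expression), rownames(pm$covariates))
  p_perm <- linear_eqtl_scan(pm$expression, g, pm$covariates, pairs)$p_nominal
  expect_lt(median(p_obs), 0.001)
  expect_gt(median(p_perm), 0.1)
})

test_that("gene-level permutation p has the right bounds and power", {
  set.seed(11)
  g <- simulate_genotypes(38, 40, maf_range = c(0.3, 0.3), seed = 13)
  expr <- matrix(rnorm(10 * 38), 10, 38,
                 dimnames = list(paste0("g", 1:10), rownames(g$dosage)))
  expr <- plant_eqtls(expr, g, data.frame(gene = "g1",
                                          variant = "var000001", beta = 2))
  pairs <- expand.grid(gene_id = paste0("g", 1:10),
                       variant_id = g$variant_id[1:4],
                       stringsAsFactors = FALSE)
  gp <- gene_level_p(expr, g, NULL, pairs, n_perms = 19, seed = 14)
  expect_true(all(gp$p_gene >= 1 / 20))
  expect_equal(gp$p_gene[gp$gene_id == "g1"], 1 / 20)
  expect_error(gene_level_p(expr, g, NULL, pairs, n_perms = 5), ">= 19")
})

test_that("LD r2 matches correlation arithmetic", {
  expect_equal(ld_r2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  expect_equal(ld_r2(c(0, 1, 2, 1), 2 - c(0, 1, 2, 1)), 1)
  expect_equal(ld_r2(c(0, 0, 2, 2), c(0, 2, 0, 2)), 0)
  expect_warning(r <- ld_r2(c(1, 1, 1), c(0, 1, 2)), "monomorphic")
  expect_true(is.na(r))
})

test_that("control matching honours every constraint or flags the test SNP", {
  g <- simulate_genotypes(120, 800, maf_range = c(0.05, 0.5),
                          ld_block_size = 4, chrom_length = 1.2e6, seed = 21)
  tests <- g$variant_id[seq(10, 400, by = 30)]
  m <- match_control_snps(tests, g, maf_tol = 0.05, max_dist = 100000,
                          r2_max = 0.2, seed = 3)
  expect_equal(nrow(m), length(tests))
  got <- m[m$matched, ]
  expect_true(all(abs(got$maf_diff) <= 0.05))
  expect_true(all(got$distance <= 100000))
  expect_true(all(got$r2 < 0.2))
  expect_false(any(got$control_variant %in% tests))
  # an isolated test SNP cannot be matched: flagged, not dropped
  iso <- manual_genotypes(cbind(rep(0:2, 10), rep(c(0L, 1L), 15)),
                          pos = c(1000L, 900000L))
  m2 <- match_control_snps("v1", iso, seed = 1)
  expect_false(m2$matched)
  expect_true(is.na(m2$control_variant))
})

test_that("effect repolarization flips swapped alleles and rejects mismatches", {
  same <- repolarize_effects(0.4, c("A", "G"), -0.1, c("A", "G"))
  expect_equal(same$beta_B, -0.1); expect_false(same$flipped)
  sw <- repolarize_effects(0.4, c("A", "G"), -0.1, c("G", "A"))
  expect_equal(sw$beta_B, 0.1); expect_true(sw$flipped)
  expect_error(repolarize_effects(0.4, c("A", "G"), 0.1, c("C", "T")),
               "excluded")
})

test_that("hypergeometric overlap matches closed forms", {
  u <- paste0("g", 1:20)
  full <- egene_overlap_test(u[1:10], u[1:10], u)
  expect_equal(full$p, 1 / choose(20, 10))
  expect_equal(full$overlap, 10)
  disj <- egene_overlap_test(u[1:5], u[6:10], u)
  expect_equal(disj$p, 1)
  expect_equal(disj$odds_ratio_raw, 0)
  # independence: OR ~ 1 on a large simulated universe
  set.seed(19)
  uni <- paste0("g", 1:20000)
  A <- sample(uni, 4000); B <- sample(uni, 4000)
  ind <- egene_overlap_test(A, B, uni)
  expect_lt(abs(ind$odds_ratio - 1), 0.15)
  expect_error(egene_overlap_test(A, B, character(0)), "empty universe")
})

test_that("qq_compare is one-sided toward smaller test p-values", {
  x <- runif(192)
  expect_equal(qq_compare(x, x)$p, 0.5, tolerance = 0.01)
  set.seed(23)
  spiked <- c(runif(162), runif(30, 0, 1e-6))
  res <- qq_compare(spiked, runif(192))
  expect_lt(res$p, 0.05)
  expect_equal(nrow(res$qq), 192)
})

test_that("VCF and dosage round-trips are lossless; missing GT rejected", {
  g <- simulate_genotypes(12, 15, seed = 31)
  vp <- file.path(tempdir(), "g.vcf")
  write_vcf(g, vp)
  back <- read_vcf(vp)
  expect_identical(unname(back$dosage), unname(g$dosage))
  expect_identical(back$pos, as.integer(g$pos))
  expect_identical(back$ref, g$ref)
  lines <- readLines(vp)
  lines[5] <- sub("(0|1)/(0|1)$", "./.", lines[5])
  writeLines(lines, vp)
  expect_error(read_vcf(vp), "missing genotype")
  dp <- file.path(tempdir(), "g.dosage.tsv")
  write_dosage(g, dp)
  b2 <- read_dosage(dp)
  expect_equal(unname(b2$dosage), unname(g$dosage))
  expect_identical(b2$variant_id, g$variant_id)
})
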