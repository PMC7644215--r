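test_that("fit_gene_nb agrees with a grid maximiser of the likelihood", {
  set.seed(101)
  for (i in 1:5) {
    mu <- 10^runif(1, -9, -7); phi <- 10^runif(1, -0.5, 1)
    off <- log(runif(10, 5e9, 5e10))
    x <- rnb_gene(10, mu, phi, off)
    if (sum(x) == 0) next
    fit <- fit_gene_nb(x, off)
    or <- nb_grid_oracle(x, off, n_grid = 200,
                         log_mu_range = log(mu) + c(-3, 3))
    ll_fit <- nb_loglik(x, off, fit$mu_hat, fit$phi_hat)
    expect_gte(ll_fit, or$loglik - 1e-6)
    expect_lt(abs(log(fit$mu_hat) - or$log_mu), 2 * or$step_mu)
    # phi may sit on a flat likelihood ridge; compare through the loglik
    ll_at_grid_phi <- nb_loglik(x, off, exp(or$log_mu), exp(or$log_phi))
    expect_gte(ll_fit, ll_at_grid_phi - 1e-6)
  }
})

test_that("NB parameters are recovered from large simulated samples", {
  set.seed(7)
  off <- log(runif(500, 5e9, 5e10))
  for (i in 1:3) {
    x <- rnb_gene(500, 1e-9, 2, off)
    fit <- fit_gene_nb(x, off)
    expect_lt(abs(fit$phi_hat / 2 - 1), 0.2)
    expect_lt(abs(fit$mu_hat / 1e-9 - 1), 0.1)
    expect_true(fit$converged)
  }
})

test_that("Poisson data drive phi to the cap; zero rows fail to converge", {
  set.seed(3)
  off <- rep(log(1e10), 200)
  x <- rpois(200, 1e10 * 1e-9 * exp(0))
  fit <- fit_gene_nb(x, off)
  expect_true(fit$capped)
  expect_lte(-log(fit$phi_hat), -13)
  z <- fit_gene_nb(rep(0L, 50), rep(log(1e10), 50))
  expect_false(z$converged)
  expect_error(fit_gene_nb(c(1L, 2L), c(0, 0)), ">= 3")
})

test_that("fit matches MASS::glm.nb on a well-behaved gene", {
  skip_if_not_installed("MASS")
  set.seed(12)
  off <- log(runif(100, 1e9, 5e10))
  x <- rnb_gene(100, 2e-9, 3, off)
  fit <- fit_gene_nb(x, off)
  gl <- MASS::glm.nb(x ~ 1 + offset(off))
  expect_equal(log(fit$mu_hat), unname(coef(gl)[1]), tolerance = 1e-4)
  expect_equal(fit$phi_hat, gl$theta, tolerance = 1e-3)
})

test_that("fit_all is offset-equivariant and sample-order invariant", {
  sim <- simulate_counts(simulation_config(n_genes = 60,
                                           n_samples_per_group = 15,
                                           n_groups = 1, seed = 21))
  cm <- sim$counts
  f1 <- fit_all(cm)
  expect_true(all(f1$converged))
  # permute samples
  perm <- sample(ncol(cm$counts))
  cm_p <- cm
  cm_p$counts <- cm$counts[, perm]
  cm_p$sample_ids <- cm$sample_ids[perm]
  cm_p$library_size <- cm$library_size[perm]
  cm_p$group <- cm$group[perm]
  f2 <- fit_all(cm_p)
  # summation order changes under permutation; agreement to optimiser tol
  expect_equal(f1$mu_hat, f2$mu_hat, tolerance = 1e-6)
  expect_equal(f1$phi_hat, f2$phi_hat, tolerance = 1e-5)
  # double every effective length: mu halves, phi unchanged
  cm_l <- cm
  cm_l$effective_length <- cm$effective_length * 2
  f3 <- fit_all(cm_l)
  expect_equal(f3$mu_hat, f1$mu_hat / 2, tolerance = 1e-6)
  expect_equal(f3$phi_hat, f1$phi_hat, tolerance = 1e-4)
})

test_that("loess residual dispersion removes its own trend", {
  lm_ <- seq(-16, -10, length.out = 120)
  fits <- data.frame(gene_id = paste0("g", 1:120),
                     mu_hat = exp(lm_), phi_hat = exp(-(2 - 0.3 * lm_)),
                     log_mean = lm_, log_overdispersion = 2 - 0.3 * lm_,
                     converged = TRUE, capped = FALSE, n_samples = 10)
  out <- loess_residual_dispersion(fits)
  expect_lt(max(abs(out$dispersion)), 1e-8)   # degree-1 loess nails a line
  expect_error(loess_residual_dispersion(fits, span = 0), "span")
  expect_error(loess_residual_dispersion(fits[1:20, ]), ">= 50")
})

test_that("planted high-variability genes get positive dispersion", {
  sim <- simulate_counts(simulation_config(n_genes = 300,
                                           n_samples_per_group = 30,
                                           frac_diff_dispersed = 0.15,
                                           dispersion_fold_change = 8,
                                           seed = 31))
  cmB <- subset_group(sim$counts, "groupB")
  fit <- loess_residual_dispersion(fit_all(cmB))
  planted <- sim$truth$diff_dispersed
  expect_gt(mean(fit$dispersion[planted], na.rm = TRUE), 0)
  expect_gt(mean(fit$dispersion[planted], na.rm = TRUE),
            mean(fit$dispersion[!planted], na.rm = TRUE))
})

test_that("bootstrap SE is reproducible and shrinks with sample size", {
  sim_n <- function(n, seed) {
    s <- simulate_counts(simulation_config(n_genes = 80,
                                           n_samples_per_group = n,
                                           n_groups = 1, seed = seed))
    s$counts
  }
  cm <- sim_n(20, 41)
  b1 <- bootstrap_se(cm, B = 2, seed = 5)
  b2 <- bootstrap_se(cm, B = 2, seed = 5)
  expect_identical(b1, b2)
  se_small <- median(bootstrap_se(cm, B = 60, seed = 6)$se_dispersion,
                     na.rm = TRUE)
  se_big <- median(bootstrap_se(sim_n(80, 41), B = 60,
                                seed = 6)$se_dispersion, na.rm = TRUE)
  expect_lt(se_big, se_small)
  expect_error(bootstrap_se(cm, B = 1), "B >= 2")
})

test_that("identical groups give zero differences and p = 1", {
  sim <- simulate_counts(simulation_config(n_genes = 80,
                                           n_samples_per_group = 10,
                                           n_groups = 1, seed = 51))
  cm <- sim$counts
  dd <- differential_dispersion_test(cm, cm, B = 30, seed = 2)
  expect_true(all(dd$abs_difference[!is.na(dd$abs_difference)] == 0))
  expect_true(all(dd$p_value[!is.na(dd$p_value)] == 1))
})

test_that("differential test flags planted genes ahead of null genes", {
  sim <- simulate_counts(simulation_config(n_genes = 150,
                                           n_samples_per_group = 25,
                                           frac_diff_dispersed = 0.1,
                                           dispersion_fold_change = 5,
                                           seed = 61))
  dd <- differential_dispersion_test(subset_group(sim$counts, "groupA"),
                                     subset_group(sim$counts, "groupB"),
                                     B = 150, seed = 3)
  j <- merge(dd, sim$truth[, c("gene_id", "diff_dispersed")], by = "gene_id")
  expect_lt(median(j$p_value[j$diff_dispersed], na.rm = TRUE),
            median(j$p_value[!j$diff_dispersed], na.rm = TRUE))
  trunc <- subset_group(sim$counts, "groupB")
  trunc$counts <- trunc$counts[1:100, ]
  trunc$gene_ids <- trunc$gene_ids[1:100]
  trunc$effective_length <- trunc$effective_length[1:100, , drop = FALSE]
  expect_error(differential_dispersion_test(
    subset_group(sim$counts, "groupA"), trunc, B = 10), "same gene set")
})

test_that("Storey and BH q-values match hand-evaluated step-up", {
  expect_equal(as.numeric(storey_qvalue(0.05, pi0 = 1)), 0.05)
  q <- storey_qvalue(c(0.01, 0.02, 0.04, 1.0), pi0 = 1)
  expect_equal(as.numeric(q), c(0.04, 0.04, 0.16 / 3, 1.0))
  expect_equal(as.numeric(q), bh_fdr(c(0.01, 0.02, 0.04, 1.0)))
  # pi0 recovery on uniform p
  set.seed(9)
  qq <- storey_qvalue(runif(10000))
  expect_gte(attr(qq, "pi0"), 0.9)
  expect_lte(attr(qq, "pi0"), 1.0)
  # q monotone in p
  p <- runif(500)
  qv <- storey_qvalue(p)
  expect_true(all(diff(qv[order(p)]) >= -1e-12))
  expect_error(storey_qvalue(numeric(0)), "empty")
  expect_error(storey_qvalue(c(0.5, 1.2)), "0, 1")
})
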