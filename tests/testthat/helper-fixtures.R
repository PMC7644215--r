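# Small fixtures built in code, shared across test files.

# count matrix with hand-set library sizes for exact CPM arithmetic
tiny_counts <- function() {
  counts <- rbind(g1 = c(100L, 250L), g2 = c(0L, 50L))
  count_matrix(counts,
               sample_ids = c("s1", "s2"),
               group = c("A", "A"),
               effective_length = cbind(A = c(1000, 500)),
               library_size = c(1e6, 5e6))
}

# a GenotypeMatrix built by hand (no simulation)
manual_genotypes <- function(dosage, pos = NULL, chrom = "chr1") {
  v <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(v) * 1000L
  ids <- paste0("v", seq_len(v))
  colnames(dosage) <- ids
  rownames(dosage) <- paste0("i", seq_len(nrow(dosage)))
  structure(list(dosage = dosage, variant_id = ids,
                 chrom = rep(chrom, v), pos = as.integer(pos),
                 ref = rep("A", v), alt = rep("G", v)),
            class = "GenotypeMatrix")
}

# NB2 counts for one gene with known parameters
rnb_gene <- function(n, mu, phi, log_offsets) {
  lam <- rgamma(n, shape = phi, rate = phi / mu)
  rpois(n, exp(log_offsets) * lam)
}

# independent grid maximiser of the NB2 likelihood (the written model),
# evaluated over a log(mu) x log(phi) grid
nb_grid_oracle <- function(x, log_offsets, n_grid = 200,
                           log_mu_range, log_phi_range = log(c(1e-3, 1e3))) {
  lmu <- seq(log_mu_range[1], log_mu_range[2], length.out = n_grid)
  lphi <- seq(log_phi_range[1], log_phi_range[2], length.out = n_grid)
  eo <- exp(log_offsets)
  best <- c(ll = -Inf, lmu = NA, lphi = NA)
  for (lp in lphi) {
    phi <- exp(lp)
    # vectorised over the mu grid: rows samples, cols mu values
    m <- outer(eo, exp(lmu))
    ll <- colSums(lgamma(x + phi) - lgamma(phi) - lgamma(x + 1) +
                    phi * (log(phi) - log(phi + m)) +
                    x * (log(m) - log(phi + m)))
    i <- which.max(ll)
    if (ll[i] > best["ll"]) best <- c(ll = ll[i], lmu = lmu[i], lphi = lp)
  }
  list(loglik = unname(best["ll"]), log_mu = unname(best["lmu"]),
       log_phi = unname(best["lphi"]),
       step_mu = diff(log_mu_range) / (n_grid - 1),
       step_phi = diff(log_phi_range) / (n_grid - 1))
}

# exact conditional HWE distribution via a different route: multinomial
# probabilities under HWE proportions, conditioned on the allele count
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  pfreq <- nA / (2 * n)
  if (pfreq == 0 || pfreq == 1) return(1)
  hw <- c(pfreq^2, 2 * pfreq * (1 - pfreq), (1 - pfreq)^2)
  hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  pr <- vapply(hs, function(h)
    dmultinom(c((nA - h) / 2, h, n - (nA - h) / 2 - h), prob = hw), 0)
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hs)]
  sum(pr[pr <= obs * (1 + 1e-9)])
}
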