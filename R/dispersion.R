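#' Fit the Gamma-Poisson model to one gene
#'
#' Maximum-likelihood fit of the negative binomial (NB2) model with known
#' per-sample offsets: counts have mean `exp(o_i) * mu` and variance
#' `m + m^2/phi`, where `o_i = log(x_i+ * l_j)` combines the sample's library
#' size and the gene's effective length. `mu` is the gene's relative
#' expression and `1/phi` its overdispersion — the excess variance across
#' individuals beyond Poisson sampling noise. The optimiser profiles `mu`
#' (Newton on log mu) inside a golden-section search on log phi; `phi` is
#' capped at 1e6 so Poisson-like genes report overdispersion `exp(-13.8)`
#' rather than diverging (flagged via `capped`).
#'
#' @param counts_row integer vector of counts for one gene.
#' @param offsets numeric vector of log-offsets `log(x_i+ * l_j)`, finite,
#'   same length as `counts_row` (>= 3 samples).
#' @return list: `mu_hat`, `phi_hat`, `converged`, `capped`.
#' @export
fit_gene_nb <- function(counts_row, offsets) {
  if (length(counts_row) < 3) stop("need >= 3 samples")
  if (length(offsets) != length(counts_row))
    stop("offsets and counts_row must have equal length")
  if (!all(is.finite(offsets))) stop("offsets must be finite")
  .nb_fit_one_cpp(as.numeric(counts_row), as.numeric(offsets))
}

#' NB2 log-likelihood with offsets
#'
#' The objective [fit_gene_nb()] maximises; exposed so independent
#' maximisers (grid search, other optimisers) can score the same surface.
#'
#' @inheritParams fit_gene_nb
#' @param mu,phi parameter values (> 0).
#' @return scalar log-likelihood.
#' @export
nb_loglik <- function(counts_row, offsets, mu, phi) {
  .nb_loglik_cpp(as.numeric(counts_row), as.numeric(offsets), mu, phi)
}

# log-offset matrix (genes x samples) for the samples of one group
offset_matrix <- function(cm) {
  len <- cm$effective_length[, cm$group, drop = FALSE]
  log(len) + rep(log(cm$library_size), each = nrow(cm$counts))
}

#' Fit the Gamma-Poisson model to every gene of one group
#'
#' One independent fit per gene with group-specific effective lengths in the
#' offsets. Single-gene failures are flagged, never fatal.
#'
#' @param counts a [count_matrix()].
#' @param group which group's samples to fit (default: the only group
#'   present; required when several are).
#' @return data.frame with one row per gene: `gene_id`, `mu_hat`, `phi_hat`,
#'   `log_mean` (log mu), `log_overdispersion` (log 1/phi), `converged`,
#'   `capped`, `n_samples`.
#' @export
fit_all <- function(counts, group = NULL) {
  stopifnot(inherits(counts, "CountMatrix"))
  grps <- unique(counts$group)
  if (is.null(group)) {
    if (length(grps) > 1)
      stop("multiple groups present; specify `group` or subset_group() first")
    group <- grps
  }
  cm <- if (length(grps) > 1) subset_group(counts, group) else counts
  fits <- .nb_fit_matrix_cpp(cm$counts + 0, offset_matrix(cm))
  data.frame(gene_id = cm$gene_ids,
             mu_hat = fits$mu_hat, phi_hat = fits$phi_hat,
             log_mean = log(fits$mu_hat),
             log_overdispersion = -log(fits$phi_hat),
             converged = fits$converged, capped = fits$capped,
             n_samples = ncol(cm$counts))
}

#' Mean-corrected dispersion: LOESS residual of overdispersion on mean
#'
#' Overdispersion is strongly tied to mean expression; the trend is removed
#' by a degree-1 LOESS of `log(1/phi)` on `log(mu)` across all converged
#' genes, and the residual is the gene's mean-corrected dispersion
#' (arbitrary units). A dispersion above 0 means more inter-individual
#' variability than genes of similar expression.
#'
#' @param fits output of [fit_all()].
#' @param span LOESS span in (0, 1] (default 0.75).
#' @return `fits` with a `dispersion` column (NA for non-converged genes and
#'   for capped genes, whose overdispersion is censored at the floor).
#' @export
loess_residual_dispersion <- function(fits, span = 0.75) {
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  # capped genes sit at the overdispersion floor: the value is censored, so
  # neither the trend fit nor a residual "dispersion" is defined for them
  ok <- fits$converged & is.finite(fits$log_mean) & !fits$capped
  if (sum(ok) < 50) stop("need >= 50 converged genes to fit the trend")
  fit <- loess(log_overdispersion ~ log_mean, data = fits[ok, ],
               degree = 1, span = span,
               control = loess.control(surface = "direct"))
  fits$dispersion <- NA_real_
  fits$dispersion[ok] <- fits$log_overdispersion[ok] - fitted(fit)
  fits
}

# one-shot dispersion vector for a raw matrix + offsets (bootstrap inner loop)
.dispersion_vector <- function(counts, log_offsets, span) {
  f <- .nb_fit_matrix_cpp(counts, log_offsets)
  d <- rep(NA_real_, nrow(counts))
  ok <- f$converged & is.finite(f$mu_hat) & f$mu_hat > 0 & !f$capped
  if (sum(ok) < 50) return(d)
  df <- data.frame(x = log(f$mu_hat), y = -log(f$phi_hat))
  tr <- tryCatch(loess(y ~ x, data = df[ok, ], degree = 1, span = span,
                       control = loess.control(surface = "direct")),
                 error = function(e) NULL)
  if (is.null(tr)) return(d)      # degenerate resample: all-NA, not fatal
  d[ok] <- df$y[ok] - fitted(tr)
  d
}

#' Bootstrap standard errors for dispersion
#'
#' Resamples the group's sample columns with replacement `B` times; each
#' resample refits every gene and refits the LOESS trend (the statistic is
#' trend-relative), and the SE is the standard deviation of the residual
#' dispersion across resamples. With `freeze_trend = TRUE` the observed
#' trend is reused — faster, documented as an approximation.
#'
#' @param counts single-group [count_matrix()] (use [subset_group()]).
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param span LOESS span.
#' @param freeze_trend reuse the observed trend instead of refitting.
#' @return data.frame: `gene_id`, `dispersion` (observed), `se_dispersion`,
#'   `unreliable` (TRUE when the gene failed to converge in > 50% of
#'   resamples).
#' @export
bootstrap_se <- function(counts, B = 1000, seed = 1L, span = 0.75,
                         freeze_trend = FALSE) {
  stopifnot(inherits(counts, "CountMatrix"), B >= 2)
  if (length(unique(counts$group)) > 1)
    stop("bootstrap_se expects a single group; subset_group() first")
  set.seed(derive_seed(seed, "bootstrap_se"))
  offs <- offset_matrix(counts)
  n <- ncol(counts$counts)
  obs_fit <- loess_residual_dispersion(fit_all(counts), span = span)
  trend0 <- NULL
  if (freeze_trend) {
    ok <- obs_fit$converged
    trend0 <- loess(log_overdispersion ~ log_mean, data = obs_fit[ok, ],
                    degree = 1, span = span,
                    control = loess.control(surface = "direct"))
  }
  draws <- matrix(NA_real_, nrow(counts$counts), B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (freeze_trend) {
      f <- .nb_fit_matrix_cpp(counts$counts[, idx, drop = FALSE] + 0,
                              offs[, idx, drop = FALSE])
      ok <- f$converged
      d <- rep(NA_real_, length(ok))
      d[ok] <- -log(f$phi_hat[ok]) -
        predict(trend0, data.frame(log_mean = log(f$mu_hat[ok])))
      draws[, b] <- d
    } else {
      draws[, b] <- .dispersion_vector(counts$counts[, idx, drop = FALSE] + 0,
                                       offs[, idx, drop = FALSE], span)
    }
  }
  n_ok <- rowSums(!is.na(draws))
  data.frame(gene_id = counts$gene_ids,
             dispersion = obs_fit$dispersion,
             se_dispersion = apply(draws, 1, sd, na.rm = TRUE),
             unreliable = n_ok < B / 2)
}

#' Differential dispersion test between two groups
#'
#' The observed statistic per gene is the absolute difference of the two
#' groups' mean-corrected dispersions. The null distribution is built by
#' pooling all sample columns of both groups and repeatedly drawing two
#' pseudo-groups of the original sizes with replacement; each iteration
#' refits every gene and the LOESS trend in both pseudo-groups and records
#' the absolute dispersion difference. The empirical p-value is
#' `(1 + #{null >= observed}) / (B + 1)` (never exactly 0), and q-values are
#' Storey's FDR estimates.
#'
#' @param counts_A,counts_B single-group [count_matrix()] objects over the
#'   same genes (each keeps its own group-specific effective lengths in the
#'   offsets).
#' @param B null resampling iterations (default 10000).
#' @param seed integer seed.
#' @param span LOESS span.
#' @return data.frame: `gene_id`, `dispersion_groupA`, `dispersion_groupB`,
#'   `abs_difference`, `p_value`, `q_value`.
#' @export
differential_dispersion_test <- function(counts_A, counts_B, B = 10000,
                                         seed = 1L, span = 0.75) {
  stopifnot(inherits(counts_A, "CountMatrix"), inherits(counts_B, "CountMatrix"))
  if (!identical(counts_A$gene_ids, counts_B$gene_ids))
    stop("the two groups must cover the same gene set")
  nA <- ncol(counts_A$counts); nB <- ncol(counts_B$counts)
  if (nA < 3 || nB < 3) stop("each group needs >= 3 samples")
  set.seed(derive_seed(seed, "diffdisp"))

  dA <- loess_residual_dispersion(fit_all(counts_A), span = span)$dispersion
  dB <- loess_residual_dispersion(fit_all(counts_B), span = span)$dispersion
  obs <- abs(dA - dB)

  pooled <- cbind(counts_A$counts, counts_B$counts) + 0
  offs <- cbind(offset_matrix(counts_A), offset_matrix(counts_B))
  ntot <- nA + nB
  exceed <- integer(length(obs))
  valid <- integer(length(obs))
  for (b in seq_len(B)) {
    ia <- sample.int(ntot, nA, replace = TRUE)
    ib <- sample.int(ntot, nB, replace = TRUE)
    da <- .dispersion_vector(pooled[, ia, drop = FALSE],
                             offs[, ia, drop = FALSE], span)
    db <- .dispersion_vector(pooled[, ib, drop = FALSE],
                             offs[, ib, drop = FALSE], span)
    nd <- abs(da - db)
    okb <- !is.na(nd) & !is.na(obs)
    valid <- valid + okb
    exceed <- exceed + (okb & nd >= obs)
  }
  p <- ifelse(valid > 0, (1 + exceed) / (valid + 1), NA_real_)
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- storey_qvalue(p[!is.na(p)])
  data.frame(gene_id = counts_A$gene_ids,
             dispersion_groupA = dA, dispersion_groupB = dB,
             abs_difference = obs, p_value = p, q_value = q)
}
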