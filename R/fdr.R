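#' Storey q-values
#'
#' Estimates the proportion of true nulls `pi0` from the flat right tail of
#' the p-value histogram — `pi0(lambda) = #{p > lambda} / (m (1 - lambda))`
#' over a lambda grid, smoothed with a cubic spline and read off at the
#' largest lambda — then scales the Benjamini-Hochberg step-up quantities:
#' `q_i = pi0 * min_{p_j >= p_i} (m p_j / rank_j)`. With fewer than 100
#' p-values the spline is unstable and a fixed `lambda = 0.5` estimate is
#' used instead. q-values are monotone non-decreasing in p.
#'
#' @param p_values p-values in \[0, 1\].
#' @param lambda_grid grid for pi0 estimation (default 0.05..0.95 by 0.05).
#' @param pi0 optional: force a pi0 value instead of estimating it
#'   (`pi0 = 1` reduces to [bh_fdr()]).
#' @return q-values in the input order; the estimated pi0 is attached as
#'   attribute `"pi0"`.
#' @export
storey_qvalue <- function(p_values, lambda_grid = seq(0.05, 0.95, by = 0.05),
                          pi0 = NULL) {
  if (length(p_values) == 0) stop("empty p-value vector")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  if (is.null(pi0)) {
    if (m < 100) {
      pi0 <- mean(p_values > 0.5) / 0.5
    } else {
      pl <- vapply(lambda_grid, function(l) mean(p_values > l) / (1 - l), 0)
      sp <- smooth.spline(lambda_grid, pl, df = 3)
      pi0 <- predict(sp, x = max(lambda_grid))$y
    }
    pi0 <- min(max(pi0, 1 / m), 1)      # clip to (0, 1]
  }
  q <- pmin(pi0 * p.adjust(p_values, method = "BH"), 1)
  attr(q, "pi0") <- pi0
  q
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up FDR; identical to [storey_qvalue()] with `pi0 = 1`.
#'
#' @inheritParams storey_qvalue
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) stop("empty p-value vector")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}
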