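#' Standardized mean differences between arms
#'
#' `SMD_j = (xbar_1j - xbar_0j) / sqrt((s2_1j + s2_0j) / 2)`, optionally
#' with weighted means and variances (ATE weights `1{A = a} / pi_a` when a
#' propensity is supplied via [balance_table()]). A covariate with zero
#' pooled variance is reported as SMD 0 and flagged.
#'
#' @param X covariate matrix.
#' @param A arm vector (0/1).
#' @param weights optional nonnegative per-row weights.
#' @return `data.table` with `variable`, `smd`, `zero_variance`.
#' @export
standardized_mean_differences <- function(X, A, weights = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(all(0:1 %in% A))
  w <- weights %||% rep(1, nrow(X))
  stat <- function(a) {
    wa <- w * (A == a)
    m <- colSums(X * wa) / sum(wa)
    v <- colSums(sweep(X, 2, m)^2 * wa) / sum(wa)
    list(m = m, v = v)
  }
  s1 <- stat(1); s0 <- stat(0)
  pool <- sqrt((s1$v + s0$v) / 2)
  zero <- pool < 1e-12
  smd <- ifelse(zero, 0, (s1$m - s0$m) / ifelse(zero, 1, pool))
  data.table(variable = colnames(X), smd = smd, zero_variance = zero)
}

#' Covariate balance table, unweighted and propensity-weighted
#'
#' Computes [standardized_mean_differences()] before weighting and under
#' ATE inverse-propensity weights `1{A=1}/pi + 1{A=0}/(1-pi)`, flagging
#' `|SMD| > threshold` (conventionally 0.1).
#'
#' @param X covariate matrix.
#' @param A arm vector.
#' @param pi_hat truncated propensity scores.
#' @param threshold flag threshold.
#' @return `data.table` with unweighted and weighted SMDs and flags.
#' @export
balance_table <- function(X, A, pi_hat, threshold = 0.1) {
  un <- standardized_mean_differences(X, A)
  w <- ifelse(A == 1, 1 / pi_hat, 1 / (1 - pi_hat))
  wt <- standardized_mean_differences(X, A, weights = w)
  data.table(variable = un$variable,
             smd_unweighted = un$smd, smd_weighted = wt$smd,
             flag_unweighted = abs(un$smd) > threshold,
             flag_weighted = abs(wt$smd) > threshold,
             zero_variance = un$zero_variance)
}

#' Arm shares as printed percentages
#'
#' @param counts named vector of arm sizes.
#' @param digits rounding of the percentage (default 1).
#' @return named vector of percentages of the total.
#' @export
arm_shares <- function(counts, digits = 1) {
  round(100 * counts / sum(counts), digits)
}
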