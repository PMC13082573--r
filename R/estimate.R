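#' Analysis configuration for effect estimation
#'
#' @param tau horizon in days (default 1826 = 5 years).
#' @param comparison ordered class pair, treated class first.
#' @param style `"intent-to-treat"` (ignore post-index switching) or
#'   `"per-protocol"` (drop switchers before fitting anything).
#' @param B bootstrap replicates (default 500).
#' @param eps propensity truncation bound.
#' @param ipcw_floor censoring positivity floor.
#' @param seed seed for fold assignment and bootstrap resampling.
#' @param ci_level confidence level.
#' @param lasso an [adaptive_lasso_spec()] shared by all nuisance fits.
#' @param survival_from_logistic internal cross-check mode: use
#'   `1 - m_a(x)` from the outcome logistic model as the conditional
#'   survival instead of the additive hazards model.
#' @param reselect_lambda re-run penalty selection inside each bootstrap
#'   replicate instead of refitting at the full-data penalty (slow;
#'   default `FALSE`).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(tau = 1826L,
                            comparison = c("insulin", "sulfonylureas"),
                            style = c("intent-to-treat", "per-protocol"),
                            B = 500L, eps = 0.01, ipcw_floor = 0.05,
                            seed = 1L, ci_level = 0.95,
                            lasso = adaptive_lasso_spec(),
                            survival_from_logistic = FALSE,
                            reselect_lambda = FALSE) {
  style <- match.arg(style)
  stopifnot(B >= 2L, ci_level > 0, ci_level < 1)
  structure(list(tau = as.integer(tau), comparison = comparison,
                 style = style, B = as.integer(B), eps = eps,
                 ipcw_floor = ipcw_floor, seed = as.integer(seed),
                 ci_level = ci_level, lasso = lasso,
                 survival_from_logistic = isTRUE(survival_from_logistic),
                 reselect_lambda = isTRUE(reselect_lambda)),
            class = "analysis_config")
}

#' AIPW estimate of the fixed-horizon risk for one arm
#'
#' `psi_a = mean( m_a(X_i) + 1{A_i = a} / pi_a(X_i) * ipcw_i * (Y_i - m_a(X_i)) )`
#' where `ipcw_i = status_known_i / K(min(T_i, tau)-)` (zero when the
#' horizon status is unknown). With no censoring, a constant true propensity
#' and `m_a` equal to the arm-a sample mean, the augmentation term cancels
#' and `psi_a` is exactly the arm-a sample mean of the outcome.
#'
#' @param A treatment vector (0/1).
#' @param pi_hat truncated propensity `P(A = 1 | X)`.
#' @param m_a outcome-model predictions for arm `a` on all rows.
#' @param y_tau fixed-horizon outcome (any value where unknown; it is
#'   multiplied by a zero weight).
#' @param ipcw weights from [ipcw_weights()].
#' @param arm the arm `a` being estimated.
#' @return list with `psi` (unclipped) and `psi_clipped` in `[0, 1]`.
#' @export
aipw_risk <- function(A, pi_hat, m_a, y_tau, ipcw, arm) {
  pi_a <- if (arm == 1) pi_hat else 1 - pi_hat
  ind <- as.numeric(A == arm)
  y0 <- y_tau * (ipcw > 0)
  psi <- mean(m_a + ind / pi_a * ipcw * (y0 - m_a))
  if (psi < 0 || psi > 1)
    ehrdr_note("AIPW risk ", signif(psi, 4), " outside [0, 1]; reporting clipped")
  list(psi = psi, psi_clipped = min(max(psi, 0), 1))
}

#' Doubly robust estimate of fixed-horizon event-free survival for one arm
#'
#' `S_a = mean( 1{A_i = a}/pi_a(X_i) * ipcw_i * (1 - Y_i) +
#' (1 - 1{A_i = a}/pi_a(X_i)) * S(tau | a, X_i) )` with the conditional
#' survival from the additive hazards model.
#'
#' @param A,pi_hat,y_tau,ipcw,arm as in [aipw_risk()].
#' @param s_cond conditional survival predictions `S(tau | a, X_i)`.
#' @return list with `s` (unclipped) and `s_clipped` in `(0, 1]` (floored at
#'   1e-6 with a note when nonpositive).
#' @export
dr_survival <- function(A, pi_hat, s_cond, y_tau, ipcw, arm) {
  pi_a <- if (arm == 1) pi_hat else 1 - pi_hat
  ind <- as.numeric(A == arm)
  y0 <- y_tau * (ipcw > 0)
  s <- mean(ind / pi_a * ipcw * (1 - y0) + (1 - ind / pi_a) * s_cond)
  if (s <= 0)
    ehrdr_note("DR survival ", signif(s, 4), " nonpositive; flooring at 1e-6")
  list(s = s, s_clipped = min(max(s, 1e-6), 1))
}

# fit every nuisance on (X, A, follow-up); lambdas may pin the penalties
# (bootstrap refits reuse the full-data selection)
fit_nuisance_bundle <- function(X, A, time_days, delta, y_tau, status_known,
                                config, lambdas = NULL, ids = NULL,
                                fit_hazards = TRUE, warm = NULL) {
  ps <- fit_propensity(X, A, spec = config$lasso, eps = config$eps,
                       lambda = lambdas$ps, ids = ids,
                       warm = warm$propensity)
  pi_hat <- predict(ps, X)
  km <- fit_censoring_km(time_days, delta, floor = config$ipcw_floor)
  ipcw <- ipcw_weights(km, time_days, status_known, tau = config$tau)
  known <- status_known == 1L
  if (!any(known & A == 1L) || !any(known & A == 0L))
    stop_ehrdr("an arm has no subjects with known horizon status")
  or <- fit_outcome_logistic(X[known, , drop = FALSE], A[known], y_tau[known],
                             weights = ipcw[known], spec = config$lasso,
                             lambda = lambdas$or, ids = ids[known],
                             warm = warm$outcome)
  m1 <- predict(or, X, a = 1)
  m0 <- predict(or, X, a = 0)
  ah <- NULL; s1 <- s0 <- NULL
  if (config$survival_from_logistic) {
    s1 <- 1 - m1; s0 <- 1 - m0
  } else if (fit_hazards) {
    ah <- fit_additive_hazards(X, A, time_days, delta, tau = config$tau,
                               spec = config$lasso, lambda = lambdas$ah,
                               ids = ids, warm = warm$hazards)
    s1 <- predict(ah, X, a = 1)
    s0 <- predict(ah, X, a = 0)
  }
  list(propensity = ps, censoring = km, outcome = or, hazards = ah,
       pi_hat = pi_hat, ipcw = ipcw, m1 = m1, m0 = m0, s1 = s1, s0 = s0,
       lambdas = list(ps = ps$fit$lambda, or = or$fit$lambda,
                      ah = if (!is.null(ah)) ah$lambda))
}

point_estimates <- function(nb, A, y_tau, estimands) {
  out <- c()
  if ("risk_difference" %in% estimands) {
    p1 <- aipw_risk(A, nb$pi_hat, nb$m1, y_tau, nb$ipcw, 1)
    p0 <- aipw_risk(A, nb$pi_hat, nb$m0, y_tau, nb$ipcw, 0)
    out <- c(out, rd = p1$psi - p0$psi, psi1 = p1$psi, psi0 = p0$psi)
  }
  if ("survival_ratio" %in% estimands) {
    s1 <- dr_survival(A, nb$pi_hat, nb$s1, y_tau, nb$ipcw, 1)
    s0 <- dr_survival(A, nb$pi_hat, nb$s0, y_tau, nb$ipcw, 0)
    out <- c(out, sr = s1$s_clipped / s0$s_clipped, S1 = s1$s, S0 = s0$s)
  }
  out
}

#' Doubly robust effect estimation with bootstrap inference
#'
#' Fits all nuisance models (adaptive-LASSO propensity and outcome logistic
#' regressions, penalized Lin-Ying additive hazards, Kaplan-Meier
#' censoring), combines them into the AIPW risk difference and the doubly
#' robust event-free survival ratio at the horizon, and attaches bootstrap
#' standard deviations, normal-approximation confidence intervals and Wald
#' p-values. Bootstrap replicates resample patients with replacement and
#' refit every nuisance with the penalty fixed at the full-data selection;
#' replicates that lose an arm (or hit a positivity failure) are redrawn and
#' counted, with an error if more than 10% of `B` must be redrawn.
#' Ratio inference is on the log scale.
#'
#' @param cohort cohort table from [build_cohort()] (or the generator's
#'   bookkeeping with the same columns).
#' @param X covariate matrix aligned to `cohort` rows.
#' @param config an [analysis_config()].
#' @param estimands subset of `c("risk_difference", "survival_ratio")`.
#' @return object of class `dr_fit`: list of `effect_estimate`s, the
#'   nuisance bundle, the (possibly switch-filtered) analysis cohort size,
#'   and the config.
#' @export
estimate_effects <- function(cohort, X, config = analysis_config(),
                             estimands = c("risk_difference", "survival_ratio")) {
  coh <- as.data.table(cohort)
  X <- as.matrix(X)
  stopifnot(nrow(coh) == nrow(X))
  ord <- order(coh$patient_id)
  coh <- coh[ord]; X <- X[ord, , drop = FALSE]
  if (config$style == "per-protocol") {
    keep <- !coh$switch
    coh <- coh[keep]; X <- X[keep, , drop = FALSE]
  }
  n <- nrow(coh)
  if (!all(0:1 %in% coh$arm)) stop_ehrdr("both arms must be present")
  A <- coh$arm
  need_ah <- "survival_ratio" %in% estimands
  nb <- fit_nuisance_bundle(X, A, coh$follow_days, coh$event, coh$y_tau,
                            coh$status_known, config, ids = coh$patient_id,
                            fit_hazards = need_ah)
  pts <- point_estimates(nb, A, coh$y_tau, estimands)

  warm <- list(propensity = nb$propensity$fit$warm,
               outcome = nb$outcome$fit$warm,
               hazards = if (need_ah && !config$survival_from_logistic)
                 nb$hazards$warm)
  est_fun <- function(idx) {
    nbb <- fit_nuisance_bundle(X[idx, , drop = FALSE], A[idx],
                               coh$follow_days[idx], coh$event[idx],
                               coh$y_tau[idx], coh$status_known[idx], config,
                               lambdas = if (config$reselect_lambda) NULL else nb$lambdas,
                               fit_hazards = need_ah, warm = warm)
    point_estimates(nbb, A[idx], coh$y_tau[idx], estimands)
  }
  reps <- boot_replicates(est_fun, A, n, config$B, config$seed,
                          has_event = coh$event)

  z <- qnorm(1 - (1 - config$ci_level) / 2)
  out <- list()
  if ("risk_difference" %in% estimands) {
    sdv <- sd(reps$points[, "rd"])
    out$risk_difference <- effect_estimate(
      estimand = "risk_difference", point = unname(pts["rd"]),
      components = c(psi1 = unname(pts["psi1"]), psi0 = unname(pts["psi0"])),
      sd = sdv, ci = unname(pts["rd"]) + c(-1, 1) * z * sdv,
      p = wald_p(unname(pts["rd"]), sdv, null = 0),
      n = n, B = config$B, seed = config$seed, style = config$style,
      redraws = reps$redraws)
  }
  if ("survival_ratio" %in% estimands) {
    lsd <- sd(log(reps$points[, "sr"]))
    pt <- unname(pts["sr"])
    out$survival_ratio <- effect_estimate(
      estimand = "survival_ratio", point = pt,
      components = c(S1 = unname(pts["S1"]), S0 = unname(pts["S0"])),
      sd = lsd, ci = exp(log(pt) + c(-1, 1) * z * lsd),
      p = wald_p(log(pt), lsd, null = 0),
      n = n, B = config$B, seed = config$seed, style = config$style,
      redraws = reps$redraws, scale = "log")
  }
  structure(list(estimates = out, nuisances = nb, n = n, config = config),
            class = "dr_fit")
}

wald_p <- function(point, sdv, null = 0) {
  if (sdv == 0) return(as.numeric(abs(point - null) > 0) * 0 + as.numeric(point == null))
  2 * pnorm(-abs(point - null) / sdv)
}

# resample patients with replacement; replicates losing an arm, losing all
# events, or erroring (e.g. positivity) are redrawn and counted
boot_replicates <- function(est_fun, arms, n, B, seed, has_event = NULL) {
  set.seed(seed)
  points <- NULL
  redraws <- 0L
  b <- 0L
  while (b < B) {
    idx <- sample.int(n, n, replace = TRUE)
    ok <- (is.null(arms) || all(0:1 %in% arms[idx])) &&
      (is.null(has_event) || any(has_event[idx] == 1L))
    pt <- if (ok) tryCatch(est_fun(idx), error = function(e) NULL) else NULL
    if (is.null(pt)) {
      redraws <- redraws + 1L
      if (redraws > 0.1 * B)
        stop_ehrdr("more than 10% of bootstrap replicates invalid (arm loss ",
                   "or positivity failures); the cohort is too fragile for ",
                   "resampling inference")
      next
    }
    b <- b + 1L
    if (is.null(points)) points <- matrix(NA_real_, B, length(pt),
                                          dimnames = list(NULL, names(pt)))
    points[b, ] <- pt
  }
  list(points = points, redraws = redraws)
}

#' Bootstrap SD, normal-approximation CI and Wald p for an estimator
#'
#' Generic patient-level nonparametric bootstrap: `estimator(idx)` must
#' return the point estimate computed on the resampled rows `idx`.
#' The SD is the sample SD of replicate points (computed on the log scale
#' when `log_scale = TRUE`, with the CI exponentiated back); the p-value is
#' the two-sided normal tail against `null`. A degenerate estimator yields
#' `SD = 0` and a point CI.
#'
#' @param estimator function of a resample index vector.
#' @param n number of rows to resample.
#' @param arms optional arm vector; replicates losing an arm are redrawn
#'   (at most 10% of `B`).
#' @param B replicates.
#' @param seed RNG seed.
#' @param ci_level confidence level.
#' @param log_scale do inference on the log scale (ratios).
#' @param null null value on the reported scale (0, or 1 for ratios).
#' @param point optional precomputed full-data point (defaults to
#'   `estimator(1:n)`).
#' @return list with `sd`, `ci`, `p`, `point`, `redraws`.
#' @export
bootstrap_ci <- function(estimator, n, arms = NULL, B = 500L, seed = 1L,
                         ci_level = 0.95, log_scale = FALSE, null = if (log_scale) 1 else 0,
                         point = NULL) {
  stopifnot(B >= 2L)
  point <- point %||% estimator(seq_len(n))
  reps <- boot_replicates(function(idx) c(est = estimator(idx)),
                          arms, n, B, seed)
  vals <- reps$points[, 1]
  z <- qnorm(1 - (1 - ci_level) / 2)
  if (log_scale) {
    sdv <- sd(log(vals))
    ci <- exp(log(point) + c(-1, 1) * z * sdv)
    p <- wald_p(log(point), sdv, null = log(null))
  } else {
    sdv <- sd(vals)
    ci <- point + c(-1, 1) * z * sdv
    p <- wald_p(point, sdv, null = null)
  }
  list(sd = sdv, ci = ci, p = p, point = point, redraws = reps$redraws)
}

#' Risk difference / survival ratio convenience wrappers
#'
#' Thin wrappers around [estimate_effects()] returning a single
#' `effect_estimate`; per-protocol style (set in `config`) drops
#' switch-flagged patients before any fitting.
#'
#' @param cohort,X,config as in [estimate_effects()].
#' @return an `effect_estimate`.
#' @export
risk_difference <- function(cohort, X, config = analysis_config()) {
  estimate_effects(cohort, X, config, estimands = "risk_difference")$estimates$risk_difference
}

#' @rdname risk_difference
#' @export
survival_ratio <- function(cohort, X, config = analysis_config()) {
  estimate_effects(cohort, X, config, estimands = "survival_ratio")$estimates$survival_ratio
}

effect_estimate <- function(estimand, point, components, sd, ci, p, n, B,
                            seed, style, redraws = 0L, scale = "identity") {
  stopifnot(p >= 0, p <= 1, ci[1] <= point + 1e-12, point <= ci[2] + 1e-12)
  structure(list(estimand = estimand, point = point, components = components,
                 sd = sd, ci = ci, p = p, n = n, B = B, seed = seed,
                 style = style, redraws = redraws, scale = scale),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  lab <- c(risk_difference = "Risk difference", survival_ratio = "Survival ratio")
  cat(sprintf("%s (%s, n = %d, B = %d): %.4f [%.4f, %.4f], p = %.3g\n",
              lab[[x$estimand]], x$style, x$n, x$B, x$point, x$ci[1], x$ci[2], x$p))
  cat(sprintf("  components: %s = %.4f, %s = %.4f; bootstrap SD%s = %.4g\n",
              names(x$components)[1], x$components[1],
              names(x$components)[2], x$components[2],
              if (x$scale == "log") " (log scale)" else "", x$sd))
  invisible(x)
}

#' @export
print.dr_fit <- function(x, ...) {
  cat("Doubly robust effect estimates (", x$config$style, ", n = ", x$n, ")\n", sep = "")
  for (e in x$estimates) print(e)
  invisible(x)
}

#' Serialize fitted nuisance models to JSON
#'
#' Writes an audit record of every nuisance component: propensity and
#' outcome coefficients with their penalties and truncation, the additive
#' hazards coefficients with the cumulative-baseline step knots, and the
#' censoring Kaplan-Meier step knots, plus an echo of the fitting spec.
#'
#' @param nuisances the `nuisances` element of a [estimate_effects()] fit.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_nuisance_json <- function(nuisances, path) {
  nb <- nuisances
  out <- list(
    propensity = list(intercept = nb$propensity$fit$intercept,
                      coef = as.list(nb$propensity$fit$coef),
                      lambda = nb$propensity$fit$lambda,
                      truncation = nb$propensity$eps),
    outcome = list(intercept = nb$outcome$fit$intercept,
                   coef = as.list(nb$outcome$fit$coef),
                   lambda = nb$outcome$fit$lambda),
    additive_hazards = if (!is.null(nb$hazards)) list(
      theta_per_year = nb$hazards$theta,
      beta_per_year = as.list(nb$hazards$beta),
      lambda = nb$hazards$lambda,
      cumulative_baseline = list(time_years = nb$hazards$Lambda0$time,
                                 value = nb$hazards$Lambda0$value)),
    censoring = list(time_days = nb$censoring$time,
                     survival = nb$censoring$surv,
                     positivity_floor = nb$censoring$floor),
    spec = unclass(nb$propensity$fit$spec)
  )
  write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null",
             pretty = TRUE)
  invisible(path)
}
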