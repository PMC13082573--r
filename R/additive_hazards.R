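# Build the Lin-Ying least-squares system on [0, tau]:
#   D = sum_i int_0^tau Y_i(t) (Z_i - Zbar(t)) (Z_i - Zbar(t))' dt
#   d = sum_i int_0^tau (Z_i - Zbar(t)) dN_i(t)
# with Y_i(t) = 1{t_i* >= t}, t_i* = min(T_i, tau) in years, Zbar(t) the
# at-risk average. Both are returned scaled by 1/n. The first term of D is
# sum_i t_i* Z_i Z_i'; the correction integrates S1 S1'/S0 over the
# inter-event intervals, where S0/S1 are at-risk sums at each distinct time.
lin_ying_system <- function(Z, tstar, event_time, is_event) {
  n <- nrow(Z)
  u <- sort(unique(tstar))
  K <- length(u)
  # at-risk aggregates at each distinct time u_k (risk set {t* >= u_k})
  idx <- findInterval(tstar, u)             # t* == u[idx]
  cnt <- tabulate(idx, K)
  S0 <- rev(cumsum(rev(cnt)))               # #at-risk at u_k
  Zsum <- rowsum(Z, group = idx, reorder = TRUE)
  full <- matrix(0, K, ncol(Z))
  full[sort(unique(idx)), ] <- Zsum
  S1 <- apply(full[K:1, , drop = FALSE], 2, cumsum)[K:1, , drop = FALSE]
  dt <- diff(c(0, u))
  D <- (crossprod(Z, Z * tstar) - crossprod(S1 * sqrt(dt / S0))) / n
  # events: d = sum over events of (Z_i - S1(t_i)/S0(t_i))
  dvec <- rep(0, ncol(Z))
  if (any(is_event)) {
    ei <- which(is_event)
    k <- findInterval(event_time[ei], u)
    Zbar_e <- S1[k, , drop = FALSE] / S0[k]
    dvec <- colSums(Z[ei, , drop = FALSE] - Zbar_e)
  }
  list(D = D, d = dvec / n, u = u, S0 = S0, S1 = S1, dt = dt)
}

# coordinate descent for 0.5 B'DB - d'B + lambda sum w_j |B_j|.
# Columns with a (near) zero diagonal carry no at-risk variation -- e.g. a
# rare indicator that became constant in a bootstrap resample -- and get a
# zero coefficient; the system is solved over the active columns.
solve_penalized_quad <- function(D, d, lambda, w, tol = 1e-10, maxit = 5000L,
                                 init = NULL) {
  p <- length(d)
  act <- diag(D) > 1e-10
  B <- rep(0, p)
  if (!all(act)) {
    if (!any(act)) return(B)
    B[act] <- solve_penalized_quad(D[act, act, drop = FALSE], d[act], lambda,
                                   w[act], tol, maxit, init[act])
    return(B)
  }
  if (lambda == 0) {
    B <- tryCatch(solve(D, d), error = function(e)
      stop_ehrdr("Lin-Ying system is singular; increase the penalty or prune columns"))
    return(as.numeric(B))
  }
  as.numeric(.cd_quad(D, d, lambda, w, init %||% rep(0, p), tol,
                      as.integer(maxit)))
}

#' Fit a (penalized) Lin-Ying additive hazards model
#'
#' Solves the closed-form Lin-Ying least-squares estimating equations for
#' the additive hazards model `lambda(t | A, X) = lambda0(t) + theta A +
#' beta' X` on follow-up restricted to `[0, tau]`, with adaptive-LASSO
#' shrinkage of the covariate block via the equivalent penalized quadratic
#' program `0.5 B'DB - d'B + lambda sum_j w_j |B_j|`. The treatment
#' coefficient is unpenalized by default. The cumulative baseline hazard is
#' the Breslow-type estimator
#' `Lambda0(t) = sum_{events <= t} dN(s)/#at-risk(s) - int_0^t B' Zbar(s) ds`,
#' projected onto nondecreasing step functions. Time is internally measured
#' in years (days / 365.25), so coefficients are events per person-year.
#'
#' The penalty is selected by K-fold cross-validation of the Lin-Ying
#' quadratic loss evaluated on the held-out fold's own (D, d) system, over a
#' geometric grid; `lambda = 0` gives the unpenalized closed-form solution.
#'
#' @param X baseline covariate matrix.
#' @param A treatment indicator (0/1).
#' @param time_days follow-up in days (> 0).
#' @param delta event indicator.
#' @param tau horizon in days.
#' @param spec an [adaptive_lasso_spec()]; the ridge initial estimator is
#'   `solve(D + ridge_lambda I, d)`.
#' @param lambda optional fixed penalty (skips cross-validation).
#' @param penalize_treatment also penalize the treatment coefficient.
#' @param ids optional patient ids for fold determinism.
#' @param warm optional warm-start coefficient vector on the standardized
#'   scale (internal bootstrap use).
#' @return object of class `additive_hazards_model`: `theta` (per year),
#'   `beta` (original scale, per year), `Lambda0` (step function knots in
#'   years and values), `lambda`, standardization info.
#' @export
fit_additive_hazards <- function(X, A, time_days, delta, tau = 1826L,
                                 spec = adaptive_lasso_spec(),
                                 lambda = NULL, penalize_treatment = FALSE,
                                 ids = NULL, warm = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X)) && ncol(X)) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  stopifnot(length(A) == n, length(time_days) == n, length(delta) == n)
  if (any(time_days <= 0)) stop_ehrdr("follow-up times must be positive")
  if (!any(delta == 1)) stop_ehrdr("no events observed")
  tau_y <- tau / DAYS_PER_YEAR
  tstar <- pmin(time_days, tau) / DAYS_PER_YEAR
  is_event <- delta == 1 & time_days <= tau

  std <- standardize_cols(X)
  Z <- cbind(A = as.numeric(A), std$Xs)
  p <- ncol(Z)
  sys <- lin_ying_system(Z, tstar, tstar, is_event)

  ridge_init <- solve(sys$D + spec$ridge_lambda * diag(p), sys$d)
  aw <- 1 / pmax(abs(ridge_init), 1e-8)^spec$gamma
  if (ncol(X)) aw[-1][std$const] <- 1e8
  if (!penalize_treatment) aw[1] <- 0

  if (is.null(lambda)) {
    pen <- which(aw > 0)
    if (!length(pen)) {
      lambda <- 0
    } else {
      lam_max <- max(abs(sys$d[pen]) / aw[pen]) * 1.05
      grid <- lam_max * exp(seq(0, log(spec$lambda_min_ratio), length.out = spec$nlambda))
      foldid <- make_foldid(n, spec$cv_folds, spec$seed, ids)
      loss <- matrix(0, spec$cv_folds, length(grid))
      for (f in seq_len(spec$cv_folds)) {
        tr <- foldid != f
        if (!any(is_event[tr]) || !any(is_event[!tr])) next
        st <- lin_ying_system(Z[tr, , drop = FALSE], tstar[tr], tstar[tr], is_event[tr])
        sv <- lin_ying_system(Z[!tr, , drop = FALSE], tstar[!tr], tstar[!tr], is_event[!tr])
        # per-fold adaptive weights: no leakage of held-out events
        rif <- solve(st$D + spec$ridge_lambda * diag(p), st$d)
        awf <- 1 / pmax(abs(rif), 1e-8)^spec$gamma
        if (!penalize_treatment) awf[1] <- 0
        for (g in seq_along(grid)) {
          B <- solve_penalized_quad(st$D, st$d, grid[g], awf, tol = 1e-8)
          loss[f, g] <- 0.5 * sum(B * (sv$D %*% B)) - sum(sv$d * B)
        }
      }
      lambda <- select_lambda(grid, loss, spec$selection)$lambda
    }
  }
  B <- solve_penalized_quad(sys$D, sys$d, lambda, aw, init = warm)
  theta <- B[1]
  beta_std <- B[-1]
  beta_std[abs(beta_std) < 1e-12] <- 0   # soft-threshold boundary dust
  beta <- if (ncol(X)) beta_std / std$sd else numeric(0)

  # Breslow-type baseline on the standardized scale, then shifted to the
  # original covariate scale and projected onto nondecreasing functions
  ev_counts <- tabulate(findInterval(tstar[is_event], sys$u), length(sys$u))
  haz_jump <- cumsum(ev_counts / sys$S0)
  drift <- cumsum(as.numeric(sys$S1 %*% B) / sys$S0 * sys$dt)
  L_std <- haz_jump - drift
  shift <- if (ncol(X)) sum(beta_std * std$mu / std$sd) else 0
  L_orig <- cummax(pmax(L_std - shift * sys$u, 0))
  structure(list(theta = theta,
                 beta = setNames(beta, colnames(X)),
                 beta_std = setNames(beta_std, colnames(X)),
                 # reported baseline: original scale, isotonically projected;
                 # predictions use the unprojected standardized-scale baseline
                 # so that they are exactly invariant to affine rescaling of X
                 Lambda0 = list(time = sys$u, value = L_orig),
                 Lambda0_std = list(time = sys$u, value = L_std),
                 lambda = lambda, tau = tau, tau_years = tau_y,
                 standardization = std[c("mu", "sd")],
                 warm = B, n = n, n_events = sum(is_event)),
            class = "additive_hazards_model")
}

# evaluate the cumulative baseline hazard step function at t (years)
eval_Lambda0 <- function(model, t) {
  k <- findInterval(t, model$Lambda0$time)
  c(0, model$Lambda0$value)[k + 1L]
}

#' Predict conditional survival from an additive hazards model
#'
#' `S(tau | a, x) = exp(-Lambda0(tau) - (theta a + beta' x) tau)`, clipped
#' to `[0, 1]`; a note is logged when more than 1% of rows are clipped.
#'
#' @param object an `additive_hazards_model`.
#' @param newdata covariate matrix.
#' @param a arm (0/1).
#' @param tau_days horizon in days (default: the fitted horizon).
#' @param ... unused.
#' @return numeric vector of survival probabilities.
#' @export
predict.additive_hazards_model <- function(object, newdata, a,
                                           tau_days = NULL, ...) {
  tau_y <- (tau_days %||% object$tau) / DAYS_PER_YEAR
  X <- as.matrix(newdata)
  lin <- object$theta * as.numeric(a)
  if (length(object$beta)) {
    Xs <- sweep(sweep(X[, names(object$beta), drop = FALSE], 2,
                      object$standardization$mu), 2,
                object$standardization$sd, "/")
    lin <- lin + as.numeric(Xs %*% object$beta_std)
  }
  k <- findInterval(tau_y, object$Lambda0_std$time)
  L0 <- c(0, object$Lambda0_std$value)[k + 1L]
  s <- exp(-(L0 + lin * tau_y))
  nclip <- sum(s > 1 | s < 0)
  if (nclip > 0.01 * length(s))
    ehrdr_note("clipping ", nclip, " of ", length(s), " survival predictions to [0, 1]")
  pmin(pmax(s, 0), 1)
}

#' @export
print.additive_hazards_model <- function(x, ...) {
  cat("Lin-Ying additive hazards model:", x$n, "subjects,", x$n_events,
      "events within tau\n")
  cat(sprintf("  theta (treatment, per year): %.5f   lambda = %.4g\n",
              x$theta, x$lambda))
  cat("  nonzero covariate coefficients:", sum(x$beta != 0), "of",
      length(x$beta), "\n")
  invisible(x)
}
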