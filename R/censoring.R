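#' Fit the Kaplan-Meier censoring model
#'
#' Product-limit estimate of the censoring-time (last-encounter)
#' distribution: censoring (`delta = 0`) is the "event" and outcome events
#' are treated as censored observations. Pooled over arms under the
#' independent-censoring assumption (fit per arm and combine externally if
#' arm-specific censoring is wanted).
#'
#' @param time_days follow-up times in days.
#' @param delta outcome event indicator (0 = censored at last encounter).
#' @param floor positivity floor; evaluating `K(t-)` below it is an error.
#' @return object of class `censoring_model` with step knots `time` and
#'   survival values `surv`.
#' @export
fit_censoring_km <- function(time_days, delta, floor = 0.05) {
  stopifnot(length(time_days) >= 1L, length(delta) == length(time_days))
  # direct product-limit computation (hot path in the bootstrap); agrees
  # with survival::survfit(Surv(time, 1 - delta) ~ 1) -- asserted in tests
  u <- sort(unique(time_days))
  k <- findInterval(time_days, u)
  at_risk <- rev(cumsum(rev(tabulate(k, length(u)))))
  cens <- tabulate(k[delta == 0], length(u))
  surv <- cumprod(1 - cens / at_risk)
  keep <- cens > 0
  structure(list(time = u[keep], surv = surv[keep],
                 floor = floor, n = length(time_days)),
            class = "censoring_model")
}

#' Evaluate the censoring survival with left limits
#'
#' Returns `K(t-)`, the probability of remaining uncensored strictly before
#' `t`; `K(0-) = 1`.
#'
#' @param model a `censoring_model`.
#' @param t times in days.
#' @param check error when any value falls below the positivity floor.
#' @return numeric vector.
#' @export
eval_censoring <- function(model, t, check = FALSE) {
  # K(t-) = value after the last censoring time strictly below t; knot times
  # are integer days, so shifting by half a day realizes the left limit
  k <- findInterval(t - 0.5, model$time)
  K <- c(1, model$surv)[k + 1L]
  if (check && any(K < model$floor))
    stop_ehrdr("censoring positivity violation: K(t-) = ",
               signif(min(K), 3), " below the floor ", model$floor)
  K
}

#' Inverse-probability-of-censoring weights at the horizon
#'
#' `w_i = status_known_i / K(min(T_i, tau)-)`; zero for subjects whose
#' fixed-horizon status is unknown. Errors if any weighted subject's
#' censoring survival falls below the positivity floor.
#'
#' @param model a `censoring_model`.
#' @param time_days follow-up in days.
#' @param status_known fixed-horizon completeness indicator.
#' @param tau horizon in days.
#' @return numeric weight vector.
#' @export
ipcw_weights <- function(model, time_days, status_known, tau = 1826L) {
  K <- eval_censoring(model, pmin(time_days, tau))
  need <- status_known == 1L
  if (any(need & K < model$floor))
    stop_ehrdr("censoring positivity violation: K(t-) = ",
               signif(min(K[need]), 3), " below the floor ", model$floor,
               " for a weighted subject")
  as.numeric(need) / K
}
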