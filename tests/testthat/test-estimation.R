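test_that("AIPW with true constant propensity reduces to the arm mean", {
  set.seed(2)
  n <- 400
  A <- rep(0:1, each = n / 2)
  y <- rbinom(n, 1, 0.3 + 0.2 * A)
  ipcw <- rep(1, n)                      # no censoring
  for (a in 0:1) {
    m_a <- rep(mean(y[A == a]), n)       # m_a = arm-specific sample mean
    psi <- aipw_risk(A, rep(0.5, n), m_a, y, ipcw, a)$psi
    expect_equal(psi, mean(y[A == a]), tolerance = 1e-14)
  }
})

test_that("AIPW on the 4-row hand fixture matches hand arithmetic", {
  A <- c(1, 0, 1, 0)
  pi <- c(0.4, 0.3, 0.8, 0.5)
  m1 <- c(0.2, 0.5, 0.3, 0.4)
  m0 <- c(0.1, 0.6, 0.2, 0.3)
  ipcw <- c(1 / 0.9, 1 / 0.8, 0, 1)      # row 3: unknown 5-year status
  y <- c(1, 0, 0, 1)
  psi1 <- aipw_risk(A, pi, m1, y, ipcw, 1)$psi
  psi0 <- aipw_risk(A, pi, m0, y, ipcw, 0)$psi
  # hand arithmetic, written out term by term
  psi1_hand <- ((0.2 + (1 / 0.4) * (1 / 0.9) * (1 - 0.2)) + 0.5 + 0.3 + 0.4) / 4
  psi0_hand <- (0.1 +
                (0.6 + (1 / 0.7) * (1 / 0.8) * (0 - 0.6)) +
                0.2 +
                (0.3 + (1 / 0.5) * 1 * (1 - 0.3))) / 4
  expect_equal(psi1, psi1_hand, tolerance = 1e-12)
  expect_equal(psi0, psi0_hand, tolerance = 1e-12)
  # and the survival side of the same fixture
  s1c <- c(0.7, 0.4, 0.6, 0.5)
  s1 <- dr_survival(A, pi, s1c, y, ipcw, 1)$s
  s1_hand <- (((1 / 0.4) * (1 / 0.9) * 0 + (1 - 1 / 0.4) * 0.7) +
              (0 + 1 * 0.4) +
              ((1 / 0.8) * 0 + (1 - 1 / 0.8) * 0.6) +
              (0 + 1 * 0.5)) / 4
  expect_equal(s1, s1_hand, tolerance = 1e-12)
})

test_that("risk and survival estimates are complementary when sharing m", {
  # no censoring + the same logistic m for both estimands => psi_a + S_a = 1
  cfg <- no_censoring(accept_config(600, seed = 42))
  sim <- simulate_cohort_data(cfg)
  coh <- bookkeeping_cohort(sim$patients)
  X <- bookkeeping_covariates(sim$patients, sim$features)
  ac <- analysis_config(B = 5, seed = 1, lasso = LASSO_FAST,
                        survival_from_logistic = TRUE)
  fit <- estimate_effects(coh, X, ac)
  rd <- fit$estimates$risk_difference
  sr <- fit$estimates$survival_ratio
  expect_equal(rd$components[["psi1"]] + sr$components[["S1"]], 1,
               tolerance = 1e-10)
  expect_equal(rd$components[["psi0"]] + sr$components[["S0"]], 1,
               tolerance = 1e-10)
})

test_that("a cohort cloned into both arms gives exactly null estimates", {
  sim <- simulate_cohort_data(no_censoring(accept_config(300, seed = 13)))
  coh1 <- bookkeeping_cohort(sim$patients)
  X1 <- bookkeeping_covariates(sim$patients, sim$features)
  # clone every patient into both arms with identical data
  clone <- function(a, tag) {
    cc <- copy(coh1)[, `:=`(arm = a, patient_id = paste0(patient_id, tag))]
    cc
  }
  coh <- rbind(clone(1L, "_t"), clone(0L, "_c"))
  X <- rbind(X1, X1)
  rownames(X) <- coh$patient_id  # note: coh order matches rbind order
  ac <- analysis_config(B = 4, seed = 7, lasso = LASSO_FAST)
  fit <- estimate_effects(coh, X, ac)
  # zero is exact at the optimum by symmetry; the tolerance reflects the
  # solvers' convergence thresholds
  expect_equal(fit$estimates$risk_difference$point, 0, tolerance = 1e-6)
  expect_equal(fit$estimates$survival_ratio$point, 1, tolerance = 1e-6)
})

test_that("estimates are invariant to row order and affine rescaling", {
  sim <- simulate_cohort_data(accept_config(600, seed = 19))
  coh <- bookkeeping_cohort(sim$patients)
  X <- bookkeeping_covariates(sim$patients, sim$features)
  ac <- analysis_config(B = 10, seed = 5, lasso = LASSO_FAST)
  base <- estimate_effects(coh, X, ac)
  set.seed(3)
  perm <- sample(nrow(coh))
  shuf <- estimate_effects(coh[perm], X[perm, , drop = FALSE], ac)
  expect_equal(shuf$estimates$risk_difference$point,
               base$estimates$risk_difference$point, tolerance = 1e-8)
  expect_equal(shuf$estimates$risk_difference$sd,
               base$estimates$risk_difference$sd, tolerance = 1e-8)
  # affine rescaling of covariates
  Xr <- sweep(sweep(X, 2, c(10, rep(1, ncol(X) - 1)), "*"), 2,
              seq_len(ncol(X)), "+")
  resc <- estimate_effects(coh, Xr, ac)
  expect_equal(resc$estimates$risk_difference$point,
               base$estimates$risk_difference$point, tolerance = 1e-6)
  expect_equal(resc$estimates$survival_ratio$point,
               base$estimates$survival_ratio$point, tolerance = 1e-6)
})

test_that("bootstrap inference is deterministic and degenerates gracefully", {
  sim <- simulate_cohort_data(accept_config(400, seed = 23))
  coh <- bookkeeping_cohort(sim$patients)
  X <- bookkeeping_covariates(sim$patients, sim$features)
  ac <- analysis_config(B = 20, seed = 11, lasso = LASSO_FAST)
  f1 <- estimate_effects(coh, X, ac, estimands = "risk_difference")
  f2 <- estimate_effects(coh, X, ac, estimands = "risk_difference")
  expect_identical(f1$estimates$risk_difference$ci,
                   f2$estimates$risk_difference$ci)
  # a constant estimator has SD 0 and a point CI
  out <- bootstrap_ci(function(idx) 0.3, n = 50, B = 25, seed = 2)
  expect_equal(out$sd, 0)
  expect_equal(out$ci, c(0.3, 0.3))
  expect_equal(out$p, 0)
})

test_that("Wald p < .05 iff the 95% CI excludes the null", {
  for (seed in 1:6) {
    sim <- simulate_cohort_data(accept_config(500, seed = 800 + seed))
    coh <- bookkeeping_cohort(sim$patients)
    X <- bookkeeping_covariates(sim$patients, sim$features)
    f <- estimate_effects(coh, X,
                          analysis_config(B = 30, seed = seed, lasso = LASSO_FAST))
    rd <- f$estimates$risk_difference
    expect_equal(rd$p < 0.05, rd$ci[1] > 0 || rd$ci[2] < 0)
    sr <- f$estimates$survival_ratio
    expect_equal(sr$p < 0.05, sr$ci[1] > 1 || sr$ci[2] < 1)
  }
})

test_that("single-arm cohorts and empty-arm queries error", {
  sim <- simulate_cohort_data(accept_config(200, seed = 3))
  coh <- bookkeeping_cohort(sim$patients)
  X <- bookkeeping_covariates(sim$patients, sim$features)
  one <- coh$arm == 1L
  expect_error(estimate_effects(coh[one], X[one, , drop = FALSE],
                                analysis_config(B = 2, lasso = LASSO_FAST)),
               "both arms")
})

test_that("per-protocol style drops switch-flagged patients before fitting", {
  sim <- simulate_cohort_data(accept_config(700, seed = 91))
  coh <- bookkeeping_cohort(sim$patients)
  X <- bookkeeping_covariates(sim$patients, sim$features)
  ac <- analysis_config(B = 4, seed = 1, lasso = LASSO_FAST,
                        style = "per-protocol")
  fit <- estimate_effects(coh, X, ac, estimands = "risk_difference")
  expect_equal(fit$n, sum(!coh$switch))
})
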