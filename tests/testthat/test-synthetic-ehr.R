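test_that("a fixed seed reproduces the event stream byte-for-byte", {
  cfg <- sim_config(n_patients = 120, seed = 20240101L)
  a <- generate_population(cfg, compute_truth = FALSE)
  b <- generate_population(cfg, compute_truth = FALSE)
  expect_identical(a$events, b$events)
  expect_identical(a$patients, b$patients)
  expect_identical(serialize(a$events, NULL), serialize(b$events, NULL))
})

test_that("oracle matches the closed form when beta = 0", {
  cfg <- sim_config(n_patients = 10, confounder_effect_on_hazard = 0,
                    baseline_hazard = 0.04, treatment_effect = 0.02,
                    death_hazard = 0, seed = 1)
  tr <- oracle_estimands(cfg, n_mc = 1e4)
  tau_y <- 1826 / 365.25  # 4.9993 years; the exp(-0.1) = 0.9048 closed form
  expect_equal(tr$true_survival_ratio, exp(-0.02 * tau_y), tolerance = 1e-10)
  expect_equal(tr$true_survival_ratio, exp(-0.1), tolerance = 1e-4)
  expect_equal(tr$true_survival[["arm1"]], exp(-0.06 * tau_y), tolerance = 1e-10)
  expect_equal(tr$true_survival[["arm0"]], exp(-0.04 * tau_y), tolerance = 1e-10)

  # null config: no effect at all
  null_cfg <- sim_config(n_patients = 10, confounder_effect_on_hazard = 0,
                         treatment_effect = 0, seed = 1)
  tr0 <- oracle_estimands(null_cfg, n_mc = 1e4)
  expect_equal(tr0$true_risk_difference, 0, tolerance = 1e-12)
  expect_equal(tr0$true_survival_ratio, 1, tolerance = 1e-12)
})

test_that("null effect without confounding gives equal arm event rates", {
  cfg <- no_censoring(sim_config(n_patients = 4000, treatment_effect = 0,
                                 confounder_effect_on_treatment = 0,
                                 confounder_effect_on_hazard = 0,
                                 switch_prob = 0, seed = 99))
  sim <- simulate_cohort_data(cfg)
  coh <- bookkeeping_cohort(sim$patients)
  p1 <- mean(coh$y_tau[coh$arm == 1]); n1 <- sum(coh$arm == 1)
  p0 <- mean(coh$y_tau[coh$arm == 0]); n0 <- sum(coh$arm == 0)
  se <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
  expect_lt(abs(p1 - p0), 3 * se)
})

test_that("no confounding by construction: treatment independent of counts", {
  # pooled over seeds; chi-square of arm vs binned top confounder count
  acc <- lapply(1:5, function(s) {
    sim <- simulate_cohort_data(sim_config(n_patients = 2000,
                                           confounder_effect_on_treatment = 0,
                                           seed = 600 + s))
    data.table(A = sim$patients$A, x = pmin(sim$patients$r01, 4L))
  })
  d <- rbindlist(acc)
  tab <- table(d$A, d$x)
  expect_gt(suppressWarnings(stats::chisq.test(tab))$p.value, 0.01)
  expect_lt(abs(mean(d$A) - 0.5), 0.02)
})

test_that("generated arm event proportions match the oracle risks", {
  # under no confounding the arm-conditional risk equals the do(a) marginal,
  # so the generator and the oracle must agree within sampling error
  cfg <- no_censoring(accept_config(5000, seed = 314))
  cfg$confounder_effect_on_treatment[] <- 0
  sim <- simulate_cohort_data(cfg)
  coh <- bookkeeping_cohort(sim$patients)
  tr <- oracle_estimands(cfg, n_mc = 2e5)
  for (a in 0:1) {
    pa <- mean(coh$y_tau[coh$arm == a])
    na <- sum(coh$arm == a)
    oracle <- unname(tr$true_risk[if (a == 1) "arm1" else "arm0"])
    se <- sqrt(pa * (1 - pa) / na + tr$mc_se$risk_difference^2)
    expect_lt(abs(pa - oracle), 3 * se + 0.005)  # 0.005: day-rounding slack
  }
})

test_that("infeasible configs are rejected after bounded resampling", {
  cfg <- sim_config(n_patients = 50,
                    confounder_effect_on_hazard = c(-0.5, -0.5, -0.5),
                    baseline_hazard = 0.02, max_resample_rounds = 3,
                    seed = 5)
  expect_error(simulate_cohort_data(cfg), "infeasible")
})

test_that("sim config validation enforces invariants", {
  expect_error(sim_config(n_patients = 0), "positive")
  expect_error(sim_config(tau = -1), "positive")
  expect_error(sim_config(comparison_classes = c("insulin", "statins")))
})

test_that("events round-trip through the CSV dialect", {
  pop <- generate_population(sim_config(n_patients = 30, seed = 2),
                             compute_truth = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(pop$events, path)
  back <- read_events(path)
  expect_equal(as.data.frame(back), as.data.frame(pop$events))
})
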