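spec0 <- covariate_spec(feature_dictionary =
                          data.table(system = "DIAG", code = "714.1",
                                     label = "ra"))

test_that("nearest-within-year lab retrieval with tie-breaking", {
  idx <- day_to_date(2000)
  ev <- mk_events(ev_row("p", 1600, "LAB", "4548-4", 7.0),
                  ev_row("p", 1970, "LAB", "4548-4", 8.1))
  row <- assemble_expert_covariates(ev, idx, spec0)
  expect_equal(unname(row["hba1c"]), 8.1)
  # only a stale measurement outside the year: missing
  ev2 <- mk_events(ev_row("p", 1600, "LAB", "4548-4", 7.0))
  expect_true(is.na(assemble_expert_covariates(ev2, idx, spec0)["hba1c"]))
  # boundary: exactly index - 365 is inside the window, index day is not
  ev3 <- mk_events(ev_row("p", 2000 - 365, "LAB", "4548-4", 6.5))
  expect_equal(unname(assemble_expert_covariates(ev3, idx, spec0)["hba1c"]), 6.5)
  ev4 <- mk_events(ev_row("p", 2000, "LAB", "4548-4", 9.9))
  expect_true(is.na(assemble_expert_covariates(ev4, idx, spec0)["hba1c"]))
  # equidistant duplicate: the later-entered row wins
  ev5 <- mk_events(ev_row("p", 1950, "LAB", "4548-4", 7.7),
                   ev_row("p", 1950, "LAB", "4548-4", 8.8))
  expect_equal(unname(assemble_expert_covariates(ev5, idx, spec0)["hba1c"]), 8.8)
})

test_that("expert covariates: durations, flags, demographics", {
  idx <- day_to_date(2000)
  ev <- mk_events(ev_row("p", 2000 - 21915, "DEMOG", "birth_date"),
                  ev_row("p", 100, "DEMOG", "sex:M"),
                  ev_row("p", 100, "DEMOG", "race:black"),
                  ev_row("p", 100, "DEMOG", "ethnicity:nonhispanic"),
                  ev_row("p", 100, "DEMOG", "residence:urban"),
                  ev_row("p", 900, "DIAG", "250.2"),
                  ev_row("p", 1500, "DIAG", "428"),
                  ev_row("p", 1800, "MED", "empagliflozin"))
  row <- assemble_expert_covariates(ev, idx, spec0,
                                    metformin_initiation = day_to_date(1700))
  expect_equal(unname(row["age"]), 21915 / 365.25)
  expect_equal(unname(row["sex_M"]), 1)
  expect_equal(unname(row["race_black"]), 1)
  expect_equal(unname(row["race_asian"]), 0)
  expect_equal(unname(row["t2d_duration"]), 1100 / 365.25)
  expect_equal(unname(row["metformin_duration"]), 300 / 365.25)
  expect_equal(unname(row["prior_hf"]), 1)
  expect_equal(unname(row["prior_sglt2i"]), 1)
  expect_true(is.na(row["bmi"]))
})

test_that("window counting partitions pre-index time", {
  idx <- day_to_date(2000)
  ev <- mk_events(ev_row("p", 1600, "DIAG", "714.1"),
                  ev_row("p", 1800, "DIAG", "714.1"),
                  ev_row("p", 1990, "DIAG", "714.1"),
                  ev_row("p", 2000 - 365, "DIAG", "714.1"),  # recent (closed left)
                  ev_row("p", 2000 - 366, "DIAG", "714.1"),  # history
                  ev_row("p", 2000, "DIAG", "714.1"))        # index day: neither
  ct <- count_window_features(ev, idx, spec0)
  expect_equal(unname(ct["ra_hist"]), 2L)    # 1600 and 1634(=2000-366)
  expect_equal(unname(ct["ra_recent"]), 3L)  # 1800, 1990, 1635(=2000-365)
  # partition property: hist + recent = all strictly-pre-index events
  expect_equal(sum(ct), 5L)
})

test_that("window partition holds on generated data", {
  pop <- generate_population(sim_config(n_patients = 40, seed = 8),
                             compute_truth = FALSE)
  dict <- default_feature_dictionary(sim_config(n_patients = 1))
  spec <- covariate_spec(feature_dictionary = dict, prevalence_threshold = 0)
  built <- build_cohort(pop$events)
  cm <- build_covariate_matrix(pop$events, built$cohort, spec,
                               episodes = built$episodes)
  idx_by <- setNames(as.integer(as.IDate(built$cohort$index_date)),
                     built$cohort$patient_id)
  ev <- pop$events[, day := as.integer(as.IDate(date))]
  for (pid in head(built$cohort$patient_id, 8)) {
    tot_pre <- nrow(ev[patient_id == pid][dict, on = c("system", "code"),
                                          nomatch = NULL][day < idx_by[[pid]]])
    hist_cols <- grep("_hist$", colnames(cm$X), value = TRUE)
    rec_cols <- grep("_recent$", colnames(cm$X), value = TRUE)
    expect_equal(sum(cm$X[pid, c(hist_cols, rec_cols)]), tot_pre)
  }
})

test_that("prevalence filter implements the >= ceiling(threshold * n) rule", {
  # 939 patients: a column present in 46 is dropped, in 47 retained
  n <- 939
  X <- cbind(at46 = c(rep(1, 46), rep(0, n - 46)),
             at47 = c(rep(1, 47), rep(0, n - 47)),
             common = rep(2, n))
  out <- prevalence_filter(X, 0.05)
  expect_equal(out$kept, c("at47", "common"))
  expect_equal(out$dropped, "at46")
  expect_equal(min_prevalence_count(0.05, 939), 47L)
  # threshold zero is vacuous
  expect_equal(ncol(prevalence_filter(X, 0)$X), 3L)
})

test_that("prevalence filter is threshold-monotone", {
  set.seed(4)
  X <- matrix(rbinom(200 * 12, 1, runif(12, 0.01, 0.5)), 200, 12,
              byrow = TRUE, dimnames = list(NULL, paste0("c", 1:12)))
  kept_prev <- colnames(X)
  for (th in c(0.01, 0.05, 0.1, 0.2, 0.5)) {
    kept <- prevalence_filter(X, th)$kept
    expect_true(all(kept %in% kept_prev))
    kept_prev <- kept
  }
})

test_that("mean imputation fills with complete-case column means", {
  X <- cbind(a = c(1, NA, 3), b = c(2, 2, 2))
  out <- impute_missing(X)
  expect_equal(unname(out$X[2, "a"]), 2)
  expect_equal(out$mask[, "a"], c(FALSE, TRUE, FALSE))
  # no missingness: identity
  X2 <- cbind(a = 1:3 / 2)
  expect_equal(impute_missing(X2)$X, X2)
  # entirely missing column: hard error naming it
  expect_error(impute_missing(cbind(bad = c(NA_real_, NA_real_))), "bad")
})

test_that("imputation preserves the observed column means", {
  set.seed(11)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  X[sample(300, 40)] <- NA
  out <- impute_missing(X)
  for (j in colnames(X))
    expect_equal(mean(out$X[, j]), mean(X[, j], na.rm = TRUE))
})

test_that("full covariate matrix has expert + filtered count columns", {
  pop <- generate_population(sim_config(n_patients = 250, seed = 21))
  built <- build_cohort(pop$events)
  spec <- covariate_spec(feature_dictionary =
                           default_feature_dictionary(sim_config(n_patients = 1)))
  cm <- build_covariate_matrix(pop$events, built$cohort, spec,
                               episodes = built$episodes)
  expect_false(anyNA(cm$X))
  expect_setequal(unique(cm$provenance),
                  c("expert", "history_window", "recent_window"))
  expect_equal(nrow(cm$X), nrow(built$cohort))
  # rare tail features of the decaying-mean dictionary must get filtered
  expect_gt(length(cm$dropped), 0L)
  # expert ages line up with bookkeeping
  bk <- pop$patients[eligible == TRUE][match(rownames(cm$X), patient_id)]
  expect_equal(unname(cm$X[, "age"]),
               (bk$index_day - bk$birth_day) / 365.25, tolerance = 1e-12)
  expect_equal(unname(cm$X[, "sex_M"]), as.numeric(bk$sexM))
})
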