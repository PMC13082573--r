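classes <- default_drug_classes()

test_that("medication pairing rule applies the 30-180 day window inclusively", {
  ev <- mk_events(ev_row("p", 10, "MED", "glipizide"),
                  ev_row("p", 80, "MED", "glipizide"))
  ep <- detect_medication_episodes(ev, classes)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$class, "sulfonylureas")
  expect_equal(as.Date(ep$initiation_date), as.Date(day_to_date(10)))
})

test_that("pairs below 30 days apart do not qualify", {
  ev <- mk_events(ev_row("p", 10, "MED", "glipizide"),
                  ev_row("p", 20, "MED", "glipizide"))
  expect_equal(nrow(detect_medication_episodes(ev, classes)), 0L)
})

test_that("all ordered pairs are scanned, earliest qualifying pair wins", {
  # days 0, 200, 260: (0,200) and (0,260) exceed 180; (200,260) qualifies
  ev <- mk_events(ev_row("p", 0, "MED", "glipizide"),
                  ev_row("p", 200, "MED", "glipizide"),
                  ev_row("p", 260, "MED", "glipizide"))
  ep <- detect_medication_episodes(ev, classes)
  expect_equal(date_to_day(ep$initiation_date), 200L)
  # boundary gaps: exactly 30 and exactly 180 both qualify
  expect_equal(ehrdr:::pair_initiation(c(0L, 30L)), 0L)
  expect_equal(ehrdr:::pair_initiation(c(0L, 180L)), 0L)
  expect_true(is.na(ehrdr:::pair_initiation(c(0L, 181L))))
  expect_true(is.na(ehrdr:::pair_initiation(c(0L, 29L))))
  expect_true(is.na(ehrdr:::pair_initiation(c(0L, 0L))))
})

test_that("unknown medication codes are ignored with a warning", {
  ev <- mk_events(ev_row("p", 10, "MED", "glipizide"),
                  ev_row("p", 80, "MED", "glipizide"),
                  ev_row("p", 15, "MED", "mystery-drug"))
  expect_warning(ep <- detect_medication_episodes(ev, classes), "mystery-drug")
  expect_equal(nrow(ep), 1L)
})

test_that("index assignment: earliest intervention wins; ties are ambiguous", {
  ep <- data.table(patient_id = "p",
                   code = c("glipizide", "insulin glargine"),
                   class = c("sulfonylureas", "insulin"),
                   initiation_date = day_to_date(c(500, 900)))
  asn <- assign_index_and_arm(ep)
  expect_equal(asn$group, "sulfonylureas")
  expect_equal(asn$arm, 0L)
  expect_equal(asn$index_date, day_to_date(500))

  # SGLT2i only: not an intervention of interest
  ep2 <- data.table(patient_id = "p", code = "empagliflozin",
                    class = "SGLT2i", initiation_date = day_to_date(500))
  expect_equal(assign_index_and_arm(ep2)$exclusion_reason,
               "no intervention-class episode")

  # same-day combination initiation
  ep3 <- data.table(patient_id = "p",
                    code = c("insulin glargine", "sitagliptin"),
                    class = c("insulin", "DPP4i"),
                    initiation_date = day_to_date(c(500, 500)))
  expect_equal(assign_index_and_arm(ep3)$exclusion_reason,
               "ambiguous combination initiation")

  # a group outside the requested comparison pair
  ep4 <- data.table(patient_id = "p", code = "sitagliptin", class = "DPP4i",
                    initiation_date = day_to_date(500))
  expect_equal(assign_index_and_arm(ep4)$exclusion_reason, "outside comparison")
  expect_equal(assign_index_and_arm(ep4, c("GLP1RA", "DPP4i"))$arm, 0L)
})

test_that("per-patient eligibility flags every failed criterion", {
  fx <- twelve_patient_fixture()
  ev <- fx$events[patient_id == "P01"]
  ep <- detect_medication_episodes(ev, classes)
  ok <- apply_eligibility(ev, ep, day_to_date(2000))
  expect_true(ok$eligible)
  expect_length(ok$reasons, 0L)

  ev3 <- fx$events[patient_id == "P03"]
  r <- apply_eligibility(ev3, detect_medication_episodes(ev3, classes),
                         day_to_date(2000))
  expect_false(r$eligible)
  expect_equal(r$reasons, "unknown age")
})

test_that("derive_outcome handles event, censoring and the horizon", {
  # observed HF within tau
  ev <- mk_events(ev_row("p", 2400, "HF_HOSP", "hf"),
                  ev_row("p", 2900, "ENCOUNTER", "visit"),
                  ev_row("p", 1900, "ENCOUNTER", "visit"))
  o <- derive_outcome(ev, day_to_date(2000))
  expect_equal(o[c("follow_days", "event", "y_tau", "status_known")],
               list(follow_days = 400L, event = 1L, y_tau = 1L,
                    status_known = 1L))
  # censored before tau: 5-year status unknown
  ev2 <- mk_events(ev_row("p", 3000, "ENCOUNTER", "visit"))
  o2 <- derive_outcome(ev2, day_to_date(2000))
  expect_equal(o2[c("follow_days", "event", "y_tau", "status_known")],
               list(follow_days = 1000L, event = 0L, y_tau = 0L,
                    status_known = 0L))
  expect_true(o2$censored_at_last_encounter)
  # death past tau: an event, but a known 5-year survivor
  ev3 <- mk_events(ev_row("p", 4000, "DEATH", "death"),
                   ev_row("p", 4000, "ENCOUNTER", "visit"))
  o3 <- derive_outcome(ev3, day_to_date(2000))
  expect_equal(o3[c("follow_days", "event", "y_tau", "status_known")],
               list(follow_days = 2000L, event = 1L, y_tau = 0L,
                    status_known = 1L))
  # an event recorded after the last encounter is censored
  ev4 <- mk_events(ev_row("p", 2500, "ENCOUNTER", "visit"),
                   ev_row("p", 2600, "HF_HOSP", "hf"))
  o4 <- derive_outcome(ev4, day_to_date(2000))
  expect_equal(o4$event, 0L)
  expect_equal(o4$follow_days, 500L)
  # contract violation: last encounter precedes index
  ev5 <- mk_events(ev_row("p", 1500, "ENCOUNTER", "visit"))
  expect_error(derive_outcome(ev5, day_to_date(2000)), "precedes")
})

test_that("switch flags require another intervention class within tau", {
  ep <- data.table(patient_id = "p",
                   code = c("glipizide", "insulin glargine", "metformin"),
                   class = c("sulfonylureas", "insulin", "metformin"),
                   initiation_date = day_to_date(c(500, 1100, 100)))
  expect_true(flag_switchers(ep, day_to_date(500), "sulfonylureas"))
  # continued metformin alone is not a switch
  expect_false(flag_switchers(ep[class != "insulin"], day_to_date(500),
                              "sulfonylureas"))
  # beyond tau is not a switch
  ep2 <- copy(ep)[class == "insulin", initiation_date := day_to_date(500 + 1827)]
  expect_false(flag_switchers(ep2, day_to_date(500), "sulfonylureas"))
  # post-index pairing rule satisfied for another class (GLP1RA -> DPP4i)
  ev <- mk_events(ev_row("q", 600, "MED", "sitagliptin"),
                  ev_row("q", 650, "MED", "sitagliptin"))
  epq <- detect_medication_episodes(ev, classes)
  expect_true(flag_switchers(epq, day_to_date(500), "GLP1RA"))
})

test_that("episode detection is insensitive to event order", {
  pop <- generate_population(sim_config(n_patients = 60, seed = 12),
                             compute_truth = FALSE)
  ev <- pop$events
  set.seed(1)
  shuf <- ev[sample(.N)]
  a <- detect_medication_episodes(ev, classes)
  b <- detect_medication_episodes(shuf, classes)
  setkey(a, patient_id, code); setkey(b, patient_id, code)
  expect_equal(a, b)
  ca <- build_cohort(ev, classes)
  cb <- build_cohort(shuf, classes)
  expect_equal(ca$cohort, cb$cohort)
})

test_that("adding an encounter never makes an eligible patient ineligible", {
  fx <- twelve_patient_fixture()
  base <- fx$events[patient_id == "P01"]
  ep <- detect_medication_episodes(base, classes)
  expect_true(apply_eligibility(base, ep, day_to_date(2000))$eligible)
  for (d in c(100L, 1990L, 2015L, 2100L, 3500L)) {
    aug <- rbind(base, mk_events(ev_row("P01", d, "ENCOUNTER", "visit")))
    expect_true(apply_eligibility(aug, ep, day_to_date(2000))$eligible)
  }
})

test_that("cohort recovery matches generator bookkeeping exactly", {
  cfg <- sim_config(n_patients = 400, switch_prob = 0.15, seed = 77)
  pop <- generate_population(cfg, compute_truth = FALSE)
  built <- build_cohort(pop$events, classes, tau = cfg$tau)
  truth <- bookkeeping_cohort(pop$patients, tau = cfg$tau)
  expect_setequal(built$cohort$patient_id, truth$patient_id)
  m <- merge(built$cohort, truth, by = "patient_id", suffixes = c("", ".t"))
  expect_identical(m$arm, m$arm.t)
  expect_identical(m$group, m$group.t)
  expect_identical(m$index_date, as.IDate(m$index_date.t))
  expect_identical(m$follow_days, m$follow_days.t)
  expect_identical(m$event, m$event.t)
  expect_identical(m$y_tau, m$y_tau.t)
  expect_identical(m$status_known, m$status_known.t)
  expect_identical(m$switch, m$switch.t)
  # ineligible patients agree too
  expect_setequal(built$exclusions$patient_id,
                  pop$patients[eligible == FALSE, patient_id])
})

test_that("per-patient operations agree with the vectorized cohort builder", {
  pop <- generate_population(sim_config(n_patients = 50, seed = 31),
                             compute_truth = FALSE)
  built <- build_cohort(pop$events, classes)
  ep_all <- built$episodes
  for (pid in head(built$cohort$patient_id, 12)) {
    evp <- pop$events[patient_id == pid]
    epp <- ep_all[patient_id == pid]
    row <- built$cohort[patient_id == pid]
    expect_true(apply_eligibility(evp, epp, row$index_date)$eligible)
    o <- derive_outcome(evp, row$index_date, tau = row$tau)
    expect_equal(o$follow_days, row$follow_days)
    expect_equal(o$event, row$event)
    expect_equal(flag_switchers(epp, row$index_date, row$group, row$tau),
                 row$switch)
  }
})
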