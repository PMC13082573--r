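library(data.table)

# tiny event-stream builder: events specified as integer day offsets
mk_events <- function(...) {
  rows <- list(...)
  rbindlist(lapply(rows, function(r)
    data.table(patient_id = r[[1]], date = day_to_date(r[[2]]),
               system = r[[3]], code = r[[4]],
               value = if (length(r) >= 5) as.numeric(r[[5]]) else NA_real_)))
}

ev_row <- function(pid, day, system, code, value = NA_real_)
  list(pid, day, system, code, value)

# standard scaffolding for an eligible patient: birth (age ~60), a
# qualifying metformin pair well before index, established/maintained care
scaffold <- function(pid, index = 2000L, age_days = 21915L,
                     arm_ingredient = "glipizide", last_enc = index + 1200L) {
  c(list(ev_row(pid, index - age_days, "DEMOG", "birth_date"),
         ev_row(pid, index - 300L, "MED", "metformin"),
         ev_row(pid, index - 240L, "MED", "metformin"),
         ev_row(pid, index - 400L, "ENCOUNTER", "visit"),
         ev_row(pid, index + 40L, "ENCOUNTER", "visit"),
         ev_row(pid, last_enc, "ENCOUNTER", "visit")),
    if (!is.null(arm_ingredient))
      list(ev_row(pid, index, "MED", arm_ingredient),
           ev_row(pid, index + 90L, "MED", arm_ingredient)))
}

# Twelve-patient fixture exercising every eligibility rule and boundary;
# expected values derived by hand from the rules (strict comparisons:
# encounters at exactly index-365 and index+30 both fail).
twelve_patient_fixture <- function() {
  idx <- 2000L
  rows <- c(
    # P01 eligible, sulfonylurea arm, censored at index+1000
    scaffold("P01", last_enc = idx + 1000L),
    # P02 age exactly <= 18 at index: (2000 - (2000-6574))/365.25 = 17.999 yr
    scaffold("P02", age_days = 6574L),
    # P03 no birth-date event
    scaffold("P03")[-1],
    # P04 only a single metformin code (no qualifying pair)
    scaffold("P04")[-3],
    # P05 metformin pair initiating ON the index date (not strictly before)
    c(scaffold("P05")[-(2:3)],
      list(ev_row("P05", idx, "MED", "metformin"),
           ev_row("P05", idx + 60L, "MED", "metformin"))),
    # P06 earliest encounter exactly at index-365: established care fails
    c(scaffold("P06")[-4],
      list(ev_row("P06", idx - 365L, "ENCOUNTER", "visit"))),
    # P07 last encounter exactly at index+30: maintained care fails
    scaffold("P07", last_enc = idx + 30L)[-5],
    # P08 boundary pass: encounters at index-366 and index+31 only
    c(scaffold("P08")[-(4:6)],
      list(ev_row("P08", idx - 366L, "ENCOUNTER", "visit"),
           ev_row("P08", idx + 31L, "ENCOUNTER", "visit"))),
    # P09 insulin and DPP4i pairs both initiating on the same day
    c(scaffold("P09", arm_ingredient = NULL),
      list(ev_row("P09", idx, "MED", "insulin glargine"),
           ev_row("P09", idx + 40L, "MED", "insulin glargine"),
           ev_row("P09", idx, "MED", "sitagliptin"),
           ev_row("P09", idx + 50L, "MED", "sitagliptin"))),
    # P10 only an SGLT2i episode: no intervention class
    c(scaffold("P10", arm_ingredient = NULL),
      list(ev_row("P10", idx, "MED", "empagliflozin"),
           ev_row("P10", idx + 60L, "MED", "empagliflozin"))),
    # P11 eligible insulin arm, HF hospitalization at index+400
    c(scaffold("P11", arm_ingredient = "insulin glargine",
               last_enc = idx + 900L),
      list(ev_row("P11", idx + 400L, "HF_HOSP", "hf_hosp"))),
    # P12 eligible sulfonylurea arm, death at index+2000 (past tau = 1826,
    # so delta = 1 but the 5-year status is a known 0); switches to insulin
    c(scaffold("P12", last_enc = idx + 2000L),
      list(ev_row("P12", idx + 2000L, "DEATH", "death"),
           ev_row("P12", idx + 600L, "MED", "insulin glargine"),
           ev_row("P12", idx + 700L, "MED", "insulin glargine")))
  )
  events <- do.call(mk_events, rows)
  expected_cohort <- data.table(
    patient_id = c("P01", "P08", "P11", "P12"),
    arm = c(0L, 0L, 1L, 0L),
    group = c("sulfonylureas", "sulfonylureas", "insulin", "sulfonylureas"),
    index_day = rep(idx, 4L),
    follow_days = c(1000L, 31L, 400L, 2000L),
    event = c(0L, 0L, 1L, 1L),
    y_tau = c(0L, 0L, 1L, 0L),
    status_known = c(0L, 0L, 1L, 1L),
    switch = c(FALSE, FALSE, FALSE, TRUE))
  expected_exclusions <- data.table(
    patient_id = c("P02", "P03", "P04", "P05", "P06", "P07", "P09", "P10"),
    exclusion_reason = c("age 18 or younger", "unknown age",
                         "no prior metformin", "no prior metformin",
                         "no established care", "no maintained care",
                         "ambiguous combination initiation",
                         "no intervention-class episode"))
  list(events = events, cohort = expected_cohort,
       exclusions = expected_exclusions)
}

# independent brute-force Lin-Ying solver: literal double loop over the
# time grid, no shared code with the package implementation
naive_lin_ying <- function(Z, time_y, event, tau_y) {
  Z <- as.matrix(Z)
  n <- nrow(Z); p <- ncol(Z)
  t_star <- pmin(time_y, tau_y)
  is_ev <- event == 1 & time_y <= tau_y
  grid <- sort(unique(t_star))
  D <- matrix(0, p, p); d <- rep(0, p)
  prev <- 0
  for (t in grid) {
    at_risk <- which(t_star >= t)
    zbar <- colMeans(Z[at_risk, , drop = FALSE])
    dt <- t - prev
    for (i in at_risk) {
      ctr <- Z[i, ] - zbar
      D <- D + dt * tcrossprod(ctr)
    }
    for (i in which(is_ev & t_star == t)) d <- d + (Z[i, ] - zbar)
    prev <- t
  }
  solve(D / n, d / n)
}
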