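#' Ingredient-level drug class map for the comparator classes
#'
#' Metformin (first line), the four second-line comparator classes (insulin,
#' sulfonylureas, DPP4i, GLP1 RA), and the classes excluded from the
#' comparisons but still tracked (SGLT2i for the prior-use baseline flag,
#' thiazolidinediones). Combination products should be mapped to all
#' constituent ingredients before entering the event stream.
#'
#' @return named list of ingredient-code character vectors.
#' @export
default_drug_classes <- function() {
  list(
    metformin = "metformin",
    insulin = c("insulin glargine", "insulin detemir", "insulin degludec",
                "insulin aspart", "insulin lispro", "insulin NPH",
                "insulin regular"),
    sulfonylureas = c("chlorpropamide", "glyburide", "glipizide",
                      "glimepiride", "tolbutamide"),
    DPP4i = c("linagliptin", "alogliptin", "saxagliptin", "sitagliptin"),
    GLP1RA = c("dulaglutide", "lixisenatide", "albiglutide", "exenatide",
               "liraglutide", "semaglutide"),
    SGLT2i = c("empagliflozin", "canagliflozin", "dapagliflozin",
               "ertugliflozin", "bexagliflozin", "sotagliflozin"),
    thiazolidinediones = c("pioglitazone", "rosiglitazone")
  )
}

# classes list -> lookup table code -> class
class_lookup <- function(classes) {
  validate_drug_classes(classes)
  rbindlist(lapply(names(classes), function(cl)
    data.table(code = classes[[cl]], class = cl)))
}

# earliest date d such that another code of the same ingredient falls in
# [d + 30, d + 180]; NA if no ordered pair qualifies. Gap bounds inclusive.
pair_initiation <- function(days, gap_min = 30L, gap_max = 180L) {
  d <- sort(as.integer(days))
  if (length(d) < 2L) return(NA_integer_)
  for (i in seq_len(length(d) - 1L)) {
    gaps <- d[(i + 1L):length(d)] - d[i]
    if (any(gaps >= gap_min & gaps <= gap_max)) return(d[i])
  }
  NA_integer_
}

#' Detect medication episodes via the 30-180 day pairing rule
#'
#' A treatment episode for an ingredient exists when any ordered pair of that
#' ingredient's medication codes is 30 to 180 days apart (bounds inclusive);
#' the initiation date is the first code of the earliest qualifying pair.
#' One episode at most is reported per (patient, ingredient). Medication
#' codes absent from the class map are ignored with a warning.
#'
#' @param events coded event table (see [read_events()]).
#' @param classes drug-class map, e.g. [default_drug_classes()].
#' @return `data.table` with columns `patient_id`, `code` (ingredient),
#'   `class`, `initiation_date`.
#' @export
detect_medication_episodes <- function(events, classes = default_drug_classes()) {
  ev <- validate_events(events)
  med <- ev[system == "MED"]
  if (!nrow(med))
    return(data.table(patient_id = character(), code = character(),
                      class = character(), initiation_date = as.IDate(integer())))
  lut <- class_lookup(classes)
  unknown <- setdiff(unique(med$code), lut$code)
  if (length(unknown)) {
    warning("ignoring MED codes not in the drug class map: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    med <- med[!code %in% unknown]
  }
  med <- med[lut, on = "code", nomatch = NULL]
  ep <- med[, .(init_day = pair_initiation(as.integer(date))),
            by = .(patient_id, code, class)]
  ep <- ep[!is.na(init_day)]
  ep[, initiation_date := as.IDate(init_day, origin = "1970-01-01")]
  setorder(ep, patient_id, initiation_date, class, code)
  ep[, .(patient_id, code, class, initiation_date)]
}

#' Assign the index date and comparison arm
#'
#' Among a patient's episodes of the four intervention classes, the earliest
#' initiation date is the index date and that episode's class is the
#' patient's group. Two different intervention classes initiating on the same
#' (earliest) date are excluded as an ambiguous combination initiation.
#' Patients whose group falls outside the requested comparison pair are
#' excluded from that comparison; arm 1 is the first class of the pair.
#'
#' @param episodes episode table from [detect_medication_episodes()]
#'   (may cover many patients).
#' @param comparison ordered pair of class names, treated class first.
#' @return `data.table` with one row per patient holding `index_date`,
#'   `group`, `arm`, and `exclusion_reason` (`NA` when assigned).
#' @export
assign_index_and_arm <- function(episodes,
                                 comparison = c("insulin", "sulfonylureas")) {
  stopifnot(length(comparison) == 2L, all(comparison %in% INTERVENTION_CLASSES))
  ep <- as.data.table(episodes)
  iv <- ep[class %in% INTERVENTION_CLASSES]
  if (!nrow(iv))
    return(data.table(patient_id = unique(ep$patient_id),
                      index_date = as.IDate(NA), group = NA_character_,
                      arm = NA_integer_,
                      exclusion_reason = "no intervention-class episode"))
  asn <- iv[, {
    first <- min(initiation_date)
    cls <- unique(class[initiation_date == first])
    if (length(cls) > 1L)
      list(index_date = as.IDate(NA), group = NA_character_, arm = NA_integer_,
           exclusion_reason = "ambiguous combination initiation")
    else if (!cls %in% comparison)
      list(index_date = as.IDate(NA), group = cls, arm = NA_integer_,
           exclusion_reason = "outside comparison")
    else
      list(index_date = first, group = cls,
           arm = as.integer(cls == comparison[1]),
           exclusion_reason = NA_character_)
  }, by = patient_id]
  none <- setdiff(unique(ep$patient_id), asn$patient_id)
  if (length(none))
    asn <- rbind(asn, data.table(patient_id = none, index_date = as.IDate(NA),
                                 group = NA_character_, arm = NA_integer_,
                                 exclusion_reason = "no intervention-class episode"))
  setorder(asn, patient_id)
  asn[]
}

#' Apply the eligibility criteria to one patient
#'
#' Eligible iff (a) age at index, from the DEMOG `birth_date` event, strictly
#' exceeds 18 years; (b) a metformin episode initiates strictly before the
#' index date; (c) at least one encounter is dated more than 365 days before
#' the index date (established care); (d) at least one encounter is dated
#' more than 30 days after the index date (maintained care). All comparisons
#' are strict, so encounters at exactly index-365 or index+30 do not qualify.
#'
#' @param events one patient's coded events.
#' @param episodes that patient's episodes from
#'   [detect_medication_episodes()].
#' @param index_date the assigned index date.
#' @return list with `eligible` (logical) and `reasons` (character vector of
#'   every failed criterion, empty when eligible).
#' @export
apply_eligibility <- function(events, episodes, index_date) {
  ev <- validate_events(events)
  idx <- as.integer(as.IDate(index_date))
  reasons <- character()
  bd <- ev[system == "DEMOG" & code == "birth_date", as.integer(date)]
  if (!length(bd)) {
    reasons <- c(reasons, "unknown age")
  } else if ((idx - min(bd)) / DAYS_PER_YEAR <= 18) {
    reasons <- c(reasons, "age 18 or younger")
  }
  ep <- as.data.table(episodes)
  met <- ep[class == "metformin"]
  if (!nrow(met) || min(as.integer(met$initiation_date)) >= idx)
    reasons <- c(reasons, "no prior metformin")
  enc <- ev[system == "ENCOUNTER", as.integer(date)]
  if (!any(enc < idx - 365L)) reasons <- c(reasons, "no established care")
  if (!any(enc > idx + 30L)) reasons <- c(reasons, "no maintained care")
  list(eligible = length(reasons) == 0L, reasons = reasons)
}

#' Derive the composite outcome and censoring for one patient
#'
#' The event time is the earlier of the first HF hospitalization strictly
#' after index and death; the censoring time is the last encounter. If the
#' event occurs on or before the last encounter it is observed (`delta = 1`),
#' otherwise follow-up is censored at the last encounter. The fixed-horizon
#' status `y_tau = 1(delta = 1 & T <= tau)` is known (`status_known = 1`)
#' exactly when the event is observed within `tau` or follow-up reaches
#' `tau`.
#'
#' @param events one patient's coded events.
#' @param index_date assigned index date.
#' @param tau horizon in days (default 1826).
#' @return list with `follow_days`, `event` (0/1),
#'   `censored_at_last_encounter`, `y_tau`, `status_known`.
#' @export
derive_outcome <- function(events, index_date, tau = 1826L) {
  ev <- validate_events(events)
  idx <- as.integer(as.IDate(index_date))
  enc <- ev[system == "ENCOUNTER", as.integer(date)]
  if (!length(enc)) stop_ehrdr("patient has no encounters")
  t_cens <- max(enc)
  if (t_cens < idx)
    stop_ehrdr("last encounter precedes the index date; ",
               "maintained-care eligibility should have excluded this patient")
  hf <- ev[system == "HF_HOSP" & as.integer(date) > idx, as.integer(date)]
  dth <- ev[system == "DEATH", as.integer(date)]
  t_event <- suppressWarnings(min(c(hf, dth)))
  if (is.finite(t_event) && t_event <= t_cens) {
    T_days <- t_event - idx; delta <- 1L; cens <- FALSE
  } else {
    T_days <- t_cens - idx; delta <- 0L; cens <- TRUE
  }
  y_tau <- as.integer(delta == 1L && T_days <= tau)
  list(follow_days = T_days, event = delta,
       censored_at_last_encounter = cens, y_tau = y_tau,
       status_known = as.integer(y_tau == 1L || T_days >= tau))
}

#' Flag post-index switching to another comparator class
#'
#' TRUE iff an episode of a different intervention class initiates in
#' `(index_date, index_date + tau]`. Continued metformin (or any
#' non-intervention class) is not a switch.
#'
#' @param episodes one patient's episodes.
#' @param index_date assigned index date.
#' @param group the patient's assigned class.
#' @param tau horizon in days.
#' @return logical.
#' @export
flag_switchers <- function(episodes, index_date, group, tau = 1826L) {
  ep <- as.data.table(episodes)
  idx <- as.integer(as.IDate(index_date))
  d <- ep[class %in% INTERVENTION_CLASSES & class != group,
          as.integer(initiation_date)]
  any(d > idx & d <= idx + tau)
}

#' Build the analyzable cohort from a coded event stream
#'
#' Vectorized orchestration of episode detection, index/arm assignment,
#' eligibility, outcome derivation and switch flagging for a whole event
#' stream. Exclusions carry a single first-failure reason in the order:
#' arm assignment (no intervention episode / ambiguous combination / outside
#' comparison), then the eligibility rules (age, prior metformin,
#' established care, maintained care).
#'
#' @param events coded event table covering all patients.
#' @param classes drug-class map.
#' @param comparison ordered class pair, treated class first.
#' @param tau horizon in days.
#' @return list with `cohort` (one row per eligible patient: `index_date`,
#'   `group`, `arm`, `follow_days`, `event`, `censored_at_last_encounter`,
#'   `y_tau`, `status_known`, `switch`, `tau`), `exclusions`
#'   (`patient_id`, `exclusion_reason`, `all_reasons`), and `episodes`.
#' @export
build_cohort <- function(events, classes = default_drug_classes(),
                         comparison = c("insulin", "sulfonylureas"),
                         tau = 1826L) {
  ev <- validate_events(events)
  ev[, day := as.integer(date)]
  episodes <- detect_medication_episodes(ev, classes)
  all_pids <- sort(unique(ev$patient_id))
  asn <- assign_index_and_arm(episodes, comparison)
  asn <- asn[data.table(patient_id = all_pids), on = "patient_id"]
  asn[is.na(exclusion_reason) & is.na(arm),
      exclusion_reason := "no intervention-class episode"]

  cand <- asn[is.na(exclusion_reason)]
  cand[, idx := as.integer(index_date)]

  # eligibility pieces, vectorized over candidate patients
  bd <- ev[system == "DEMOG" & code == "birth_date",
           .(birth_day = min(day)), by = patient_id]
  cand <- bd[cand, on = "patient_id"]
  met <- episodes[class == "metformin",
                  .(met_day = min(as.integer(initiation_date))), by = patient_id]
  cand <- met[cand, on = "patient_id"]
  enc <- ev[system == "ENCOUNTER", .(patient_id, day)][cand[, .(patient_id, idx)],
                                                       on = "patient_id"]
  encs <- enc[, .(established = any(day < idx - 365L),
                  maintained = any(day > idx + 30L),
                  last_enc = max(day)), by = patient_id]
  cand <- encs[cand, on = "patient_id"]

  cand[, age_ok := !is.na(birth_day) & (idx - birth_day) / DAYS_PER_YEAR > 18]
  cand[, met_ok := !is.na(met_day) & met_day < idx]
  cand[, est_ok := isTRUE_v(established)]
  cand[, mnt_ok := isTRUE_v(maintained)]
  cand[, first_fail := fifelse(is.na(birth_day), "unknown age",
                        fifelse(!age_ok, "age 18 or younger",
                         fifelse(!met_ok, "no prior metformin",
                          fifelse(!est_ok, "no established care",
                           fifelse(!mnt_ok, "no maintained care", NA_character_)))))]
  cand[, all_reasons := paste_reasons(is.na(birth_day), age_ok, met_ok, est_ok, mnt_ok)]

  elig <- cand[is.na(first_fail)]

  # outcomes for eligible patients
  hf <- ev[system == "HF_HOSP", .(patient_id, day)][elig[, .(patient_id, idx)],
                                                    on = "patient_id", nomatch = NULL]
  hf <- hf[day > idx]
  hf <- if (nrow(hf)) hf[, .(hf_day = min(day)), by = patient_id]
        else data.table(patient_id = character(), hf_day = integer())
  dth <- ev[system == "DEATH"]
  dth <- if (nrow(dth)) dth[, .(death_day = min(day)), by = patient_id]
         else data.table(patient_id = character(), death_day = integer())
  elig <- hf[elig, on = "patient_id"]
  elig <- dth[elig, on = "patient_id"]
  elig[, t_event := pmin(fifelse(is.na(hf_day), Inf, as.numeric(hf_day)),
                         fifelse(is.na(death_day), Inf, as.numeric(death_day)))]
  elig[, `:=`(event = as.integer(is.finite(t_event) & t_event <= last_enc))]
  elig[, follow_days := as.integer(fifelse(event == 1L, t_event - idx,
                                           as.numeric(last_enc - idx)))]
  elig[, censored_at_last_encounter := event == 0L]
  elig[, y_tau := as.integer(event == 1L & follow_days <= tau)]
  elig[, status_known := as.integer(y_tau == 1L | follow_days >= tau)]

  # switch flags from episodes
  sw <- episodes[class %in% INTERVENTION_CLASSES][elig[, .(patient_id, idx, group)],
                                                  on = "patient_id", nomatch = NULL]
  sw <- sw[class != group & as.integer(initiation_date) > idx &
             as.integer(initiation_date) <= idx + tau,
           .(switch = TRUE), by = patient_id]
  elig <- sw[elig, on = "patient_id"]
  elig[is.na(switch), switch := FALSE]

  cohort <- elig[, .(patient_id, index_date, group, arm, follow_days, event,
                     censored_at_last_encounter, y_tau, status_known, switch,
                     tau = as.integer(tau))]
  setorder(cohort, patient_id)
  stopifnot(all(cohort$follow_days >= 0L),
            all(cohort$event %in% 0:1),
            !any(cohort$event == 1L & cohort$censored_at_last_encounter))

  exclusions <- rbind(
    asn[!is.na(exclusion_reason),
        .(patient_id, exclusion_reason, all_reasons = exclusion_reason)],
    cand[!is.na(first_fail),
         .(patient_id, exclusion_reason = first_fail, all_reasons)])
  setorder(exclusions, patient_id)
  list(cohort = cohort, exclusions = exclusions, episodes = episodes)
}

isTRUE_v <- function(x) !is.na(x) & x

paste_reasons <- function(no_bd, age_ok, met_ok, est_ok, mnt_ok) {
  if (!length(no_bd)) return(character(0))
  mapply(function(b, a, m, e, mt) {
    r <- c(if (b) "unknown age" else if (!a) "age 18 or younger",
           if (!m) "no prior metformin",
           if (!e) "no established care",
           if (!mt) "no maintained care")
    if (is.null(r)) NA_character_ else paste(r, collapse = "; ")
  }, no_bd, age_ok, met_ok, est_ok, mnt_ok, USE.NAMES = FALSE)
}

#' Write the cohort (with exclusions) to CSV
#'
#' One row per patient; ineligible patients carry their first-failure
#' `exclusion_reason` and empty analysis columns.
#'
#' @param built result of [build_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(built, path) {
  coh <- copy(built$cohort)[, exclusion_reason := NA_character_]
  exc <- copy(built$exclusions)[, `:=`(index_date = as.IDate(NA),
                                       group = NA_character_, arm = NA_integer_,
                                       follow_days = NA_integer_, event = NA_integer_,
                                       censored_at_last_encounter = NA,
                                       y_tau = NA_integer_, status_known = NA_integer_,
                                       switch = NA, tau = NA_integer_)]
  exc[, all_reasons := NULL]
  out <- rbind(coh, exc, use.names = TRUE)
  setorder(out, patient_id)
  fwrite(out, path)
  invisible(path)
}
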