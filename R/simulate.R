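#' Configuration of the synthetic EHR generator
#'
#' Describes a complete synthetic world: a population of metformin-treated
#' type 2 diabetes patients who initiate one of two second-line drug classes,
#' with treatment assignment confounded by overdispersed baseline code counts,
#' a composite heart-failure-hospitalization-or-death outcome generated from a
#' constant-in-time additive hazards model, and censoring at the last
#' encounter of an independent visit process.
#'
#' The hazard of HF hospitalization for a patient with count vector `x` in
#' arm `a` is `lambda0 + theta * a + beta' x` (events per person-year); death
#' is a competing exponential draw with rate `death_hazard`, and the composite
#' primary event is the earlier of the two. Covariate counts are negative
#' binomial with geometrically decaying means `count_mu * count_decay^(j-1)`,
#' so late dictionary features are rare and the downstream prevalence filter
#' has something to remove.
#'
#' @param n_patients number of patients.
#' @param n_history_features,n_recent_features number of dictionary code
#'   features whose counts are laid down, respectively, more than one year
#'   before the index date and within the year before it.
#' @param confounder_effect_on_treatment numeric vector of log-odds of
#'   treatment per unit count, recycled/padded to
#'   `n_recent_features + n_history_features` (recent features first).
#' @param confounder_effect_on_hazard numeric vector of additive hazard per
#'   unit count (events per person-year), same layout.
#' @param baseline_hazard `lambda0`, events per person-year.
#' @param treatment_effect `theta`, additive hazard difference of arm 1 minus
#'   arm 0 (events per person-year).
#' @param death_hazard competing death hazard (events per person-year).
#' @param censoring_mean_years mean of the exponential last-encounter
#'   (loss-to-follow-up) time, measured from the index date.
#' @param admin_horizon_years administrative truncation of follow-up, years.
#' @param encounter_rate encounters per person-year of the visit process.
#' @param index_spacing length-2 vector: uniform min/max days between
#'   metformin initiation and second-line initiation.
#' @param tau outcome horizon in days (default 1826 = 5 years incl. leap day).
#' @param treated_share target marginal share of arm 1 used to center the
#'   treatment-assignment intercept.
#' @param demog_effect_on_treatment named vector `c(age = , sexM = )` of
#'   log-odds effects (age centered at `age_mean`); zero by default so that
#'   setting `confounder_effect_on_treatment = 0` yields a randomized world.
#' @param count_mu,count_decay,nb_size negative-binomial count means
#'   `count_mu * count_decay^(j-1)` and common size (dispersion) parameter.
#' @param switch_prob probability of post-index switching to a different
#'   comparator class.
#' @param lab_missingness probability that a baseline lab has no measurement
#'   within the year before index.
#' @param prior_hf_prob,prior_sglt2i_prob prevalence of pre-index HF
#'   diagnosis and pre-index SGLT2i use.
#' @param female_share,age_mean,age_sd,age_min,age_max demographics.
#' @param comparison_classes ordered pair of drug classes; arm 1 is the first.
#' @param max_resample_rounds bound on reject-and-resample rounds for
#'   patients whose sampled covariates would make a hazard negative.
#' @param seed integer RNG seed; a fixed seed makes [generate_population()]
#'   byte-reproducible.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 1000L,
                       n_history_features = 20L,
                       n_recent_features = 20L,
                       confounder_effect_on_treatment = NULL,
                       confounder_effect_on_hazard = NULL,
                       baseline_hazard = 0.03,
                       treatment_effect = 0.02,
                       death_hazard = 0.01,
                       censoring_mean_years = 30,
                       admin_horizon_years = 10,
                       encounter_rate = 4,
                       index_spacing = c(90, 720),
                       tau = 1826L,
                       treated_share = 0.5,
                       demog_effect_on_treatment = c(age = 0, sexM = 0),
                       count_mu = 2,
                       count_decay = 0.85,
                       nb_size = 1.2,
                       switch_prob = 0.10,
                       lab_missingness = 0.2,
                       prior_hf_prob = 0.05,
                       prior_sglt2i_prob = 0.01,
                       female_share = 0.44,
                       age_mean = 60, age_sd = 10,
                       age_min = 19, age_max = 90,
                       comparison_classes = c("insulin", "sulfonylureas"),
                       max_resample_rounds = 50L,
                       seed = 20240101L) {
  nf <- n_recent_features + n_history_features
  pad <- function(v, default = 0) {
    if (is.null(v)) v <- default
    v <- as.numeric(v)
    if (length(v) < nf) v <- c(v, rep(0, nf - length(v)))
    v[seq_len(nf)]
  }
  # YAML round-trips drop names on atomic vectors; restore the layout
  demog_effect_on_treatment <- as.numeric(demog_effect_on_treatment)
  length(demog_effect_on_treatment) <- 2L
  demog_effect_on_treatment[is.na(demog_effect_on_treatment)] <- 0
  names(demog_effect_on_treatment) <- c("age", "sexM")
  # defaults: mild confounding on the first three recent-window features
  if (is.null(confounder_effect_on_treatment))
    confounder_effect_on_treatment <- c(0.4, 0.3, 0.2)
  if (is.null(confounder_effect_on_hazard))
    confounder_effect_on_hazard <- c(0.012, 0.008, 0.005)
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_history_features = as.integer(n_history_features),
    n_recent_features = as.integer(n_recent_features),
    confounder_effect_on_treatment = pad(confounder_effect_on_treatment),
    confounder_effect_on_hazard = pad(confounder_effect_on_hazard),
    baseline_hazard = baseline_hazard,
    treatment_effect = treatment_effect,
    death_hazard = death_hazard,
    censoring_mean_years = censoring_mean_years,
    admin_horizon_years = admin_horizon_years,
    encounter_rate = encounter_rate,
    index_spacing = as.numeric(index_spacing),
    tau = as.integer(tau),
    treated_share = treated_share,
    demog_effect_on_treatment = demog_effect_on_treatment,
    count_mu = count_mu, count_decay = count_decay, nb_size = nb_size,
    switch_prob = switch_prob,
    lab_missingness = lab_missingness,
    prior_hf_prob = prior_hf_prob,
    prior_sglt2i_prob = prior_sglt2i_prob,
    female_share = female_share,
    age_mean = age_mean, age_sd = age_sd,
    age_min = age_min, age_max = age_max,
    comparison_classes = comparison_classes,
    max_resample_rounds = as.integer(max_resample_rounds),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_patients <= 0L) stop_ehrdr("n_patients must be positive")
  if (cfg$tau <= 0L) stop_ehrdr("tau must be positive")
  if (cfg$baseline_hazard <= 0) stop_ehrdr("baseline_hazard must be > 0")
  if (cfg$baseline_hazard + min(0, cfg$treatment_effect) < 0)
    stop_ehrdr("baseline hazard plus treatment effect is negative")
  if (length(cfg$index_spacing) != 2L || diff(cfg$index_spacing) < 0)
    stop_ehrdr("index_spacing must be c(min, max) days")
  if (!all(cfg$comparison_classes %in% INTERVENTION_CLASSES))
    stop_ehrdr("comparison_classes must be two of: ",
               paste(INTERVENTION_CLASSES, collapse = ", "))
  invisible(cfg)
}

# Feature dictionary implied by a sim_config: multi-system synthetic codes,
# recent-window features first.
sim_feature_table <- function(cfg) {
  systems <- c("DIAG", "LAB", "PROC", "NOTE_CUI")
  mk <- function(n, tag) {
    if (n == 0L) return(NULL)
    j <- seq_len(n)
    data.table(
      system = systems[(j - 1L) %% length(systems) + 1L],
      code = sprintf("%s%02d", tag, j),
      label = sprintf("%s%02d", tolower(tag), j),
      window = if (tag == "R") "recent" else "history",
      mu = cfg$count_mu * cfg$count_decay^(j - 1L)
    )
  }
  rbindlist(list(mk(cfg$n_recent_features, "R"),
                 mk(cfg$n_history_features, "H")))
}

#' Feature dictionary matching the synthetic generator
#'
#' Returns the `(system, code, label)` dictionary that
#' [generate_population()] emits count events for, in the layout expected by
#' [covariate_spec()].
#'
#' @param config a [sim_config()].
#' @return a `data.table` with columns `system`, `code`, `label`.
#' @export
default_feature_dictionary <- function(config = sim_config()) {
  sim_feature_table(config)[, .(system, code, label)]
}

# Draw NB count matrices with reject-and-resample so that both potential
# hazards stay nonnegative for every patient. Returns n x nf matrix.
draw_counts <- function(n, cfg) {
  feats <- sim_feature_table(cfg)
  nf <- nrow(feats)
  beta <- cfg$confounder_effect_on_hazard
  draw <- function(m) {
    matrix(rnbinom(m * nf, mu = rep(feats$mu, each = m), size = cfg$nb_size),
           nrow = m, ncol = nf)
  }
  X <- draw(n)
  worst_arm <- min(0, cfg$treatment_effect)
  bad <- which(cfg$baseline_hazard + worst_arm + X %*% beta <= 0)
  round <- 0L
  while (length(bad)) {
    round <- round + 1L
    if (round > cfg$max_resample_rounds)
      stop_ehrdr("hazard remained negative after ", cfg$max_resample_rounds,
                 " resampling rounds; the sim_config is infeasible")
    X[bad, ] <- draw(length(bad))
    bad <- bad[cfg$baseline_hazard + worst_arm + X[bad, , drop = FALSE] %*% beta <= 0]
  }
  X
}

#' Draw an analysis-ready synthetic population (tabular fast path)
#'
#' Performs all random draws of the generator -- demographics, code counts,
#' confounded treatment assignment, additive-hazards event times, competing
#' death, last-encounter censoring, switching, baseline labs -- and returns
#' them in tabular form, without rendering the coded event stream.
#' [generate_population()] renders exactly these draws into events, so the
#' tabular `patients` table is also the generator's ground-truth bookkeeping
#' for cohort-recovery tests, and serves as a fast path for simulation
#' studies that do not exercise the cohort builder.
#'
#' Note `set.seed(config$seed)` is called internally.
#'
#' @param config a [sim_config()].
#' @return a list with elements `patients` (one row per patient, including
#'   the count matrix columns, true arm, follow-up, event indicator,
#'   eligibility and switch flags), `features` (dictionary with windows), and
#'   `config`.
#' @export
simulate_cohort_data <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  simulate_cohort_draw(config)
}

# The actual draws; assumes the RNG state has been set by the caller.
simulate_cohort_draw <- function(cfg) {
  n <- cfg$n_patients
  feats <- sim_feature_table(cfg)

  # demographics
  age <- pmin(pmax(rnorm(n, cfg$age_mean, cfg$age_sd), cfg$age_min), cfg$age_max)
  sexM <- rbinom(n, 1L, 1 - cfg$female_share)
  race <- sample(c("white", "black", "asian", "other"), n, replace = TRUE,
                 prob = c(0.83, 0.09, 0.07, 0.01))
  hispanic <- rbinom(n, 1L, 0.02)
  rural <- rbinom(n, 1L, 0.02)

  # care timeline (integer day offsets from the epoch)
  index_day <- sample(1500:3000, n, replace = TRUE)
  spacing <- round(runif(n, cfg$index_spacing[1], cfg$index_spacing[2]))
  extra <- round(runif(n, 30, 400))
  m0_day <- index_day - spacing
  care_start_day <- index_day - (365L + spacing + extra)
  birth_day <- index_day - round(age * DAYS_PER_YEAR)

  # counts and treatment assignment
  X <- draw_counts(n, cfg)
  colnames(X) <- feats$label
  alpha <- cfg$confounder_effect_on_treatment
  dem <- cfg$demog_effect_on_treatment
  alpha0 <- logit(cfg$treated_share) - sum(alpha * feats$mu)
  lp <- alpha0 + as.numeric(X %*% alpha) +
    dem[["age"]] * (age - cfg$age_mean) + dem[["sexM"]] * sexM
  A <- rbinom(n, 1L, expit(lp))

  # event times (years) from the additive hazards model + competing death
  haz <- cfg$baseline_hazard + cfg$treatment_effect * A + as.numeric(X %*% cfg$confounder_effect_on_hazard)
  t_hf <- rexp(n, rate = haz)
  t_death <- if (cfg$death_hazard > 0) rexp(n, rate = cfg$death_hazard) else rep(Inf, n)
  hf_day <- index_day + pmax(1, round(t_hf * DAYS_PER_YEAR))
  death_day <- ifelse(is.finite(t_death),
                      index_day + pmax(1, round(t_death * DAYS_PER_YEAR)), Inf)

  # censoring: last-encounter time, exponential truncated at the horizon
  c_yrs <- pmin(rexp(n, rate = 1 / cfg$censoring_mean_years),
                cfg$admin_horizon_years)
  cens_day <- index_day + pmax(1, round(c_yrs * DAYS_PER_YEAR))

  # observation window ends at the earlier of loss to follow-up and death
  w_day <- pmin(cens_day, death_day)
  event_day <- pmin(hf_day, death_day)
  delta <- as.integer(event_day <= w_day)
  T_days <- as.integer(pmin(event_day, w_day) - index_day)
  event_is_hf <- delta == 1L & hf_day <= death_day
  y_tau <- as.integer(delta == 1L & T_days <= cfg$tau)
  status_known <- as.integer(y_tau == 1L | T_days >= cfg$tau)
  # only maintained care (an encounter > 30 days post index) can fail by
  # construction; the last encounter is at w_day
  eligible <- (w_day - index_day) >= 31L

  # treatment switching after index
  switch <- rbinom(n, 1L, cfg$switch_prob)
  switch_off <- round(runif(n, 90, cfg$tau - 181))
  switch_day <- ifelse(switch == 1L, index_day + switch_off, NA_integer_)
  arm_class <- ifelse(A == 1L, cfg$comparison_classes[1], cfg$comparison_classes[2])
  other <- lapply(arm_class, function(cl) setdiff(INTERVENTION_CLASSES, cl))
  switch_class <- ifelse(switch == 1L,
                         vapply(other, function(o) o[sample.int(length(o), 1L)], ""),
                         NA_character_)

  # baseline labs / BMI: value of the measurement closest to index (or NA)
  lab_draw <- function(mean, sdv) {
    present <- rbinom(n, 1L, 1 - cfg$lab_missingness)
    ifelse(present == 1L, rnorm(n, mean, sdv), NA_real_)
  }
  hba1c <- lab_draw(8.2, 1.5); ldl <- lab_draw(95, 30)
  hdl <- lab_draw(45, 12); tchol <- lab_draw(180, 35)
  bmi_present <- rbinom(n, 1L, 0.9)
  bmi <- ifelse(bmi_present == 1L, rnorm(n, 32, 6), NA_real_)

  prior_hf <- rbinom(n, 1L, cfg$prior_hf_prob)
  prior_sglt2i <- rbinom(n, 1L, cfg$prior_sglt2i_prob)
  t2d_day <- care_start_day + round(runif(n, 0, pmax(1, m0_day - care_start_day)))

  classes <- default_drug_classes()
  pick_ing <- function(cl) {
    ing <- classes[[cl]]
    ing[sample.int(length(ing), 1L)]
  }
  patients <- data.table(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = age, sexM = sexM, race = race, hispanic = hispanic, rural = rural,
    birth_day = birth_day, care_start_day = care_start_day,
    index_day = index_day, m0_day = m0_day, t2d_day = t2d_day,
    A = A, arm_class = arm_class,
    arm_ingredient = vapply(arm_class, pick_ing, ""),
    lp_treat = lp,
    hf_day = hf_day, death_day = death_day, cens_day = cens_day,
    w_day = as.integer(w_day), event_day = event_day,
    T_days = T_days, delta = delta, event_is_hf = event_is_hf,
    y_tau = y_tau, status_known = status_known, eligible = eligible,
    switch = switch, switch_day = as.integer(switch_day),
    switch_class = switch_class,
    switch_ingredient = ifelse(switch == 1L,
                               vapply(ifelse(is.na(switch_class), "insulin",
                                             switch_class), pick_ing, ""),
                               NA_character_),
    hba1c = hba1c, ldl = ldl, hdl = hdl, total_cholesterol = tchol, bmi = bmi,
    prior_hf = prior_hf, prior_sglt2i = prior_sglt2i,
    met_gap = sample(30:180, n, replace = TRUE),
    arm_gap = sample(30:180, n, replace = TRUE),
    switch_gap = sample(30:180, n, replace = TRUE)
  )
  list(patients = cbind(patients, as.data.table(X)),
       features = feats, config = cfg)
}

# Render the tabular draws into a long coded event stream.
render_events <- function(sim) {
  cfg <- sim$config
  p <- sim$patients
  feats <- sim$features
  n <- nrow(p)
  ev <- list()
  add <- function(pid, day, system, code, value = NA_real_) {
    if (!length(pid)) return(invisible(NULL))
    ev[[length(ev) + 1L]] <<- data.table(
      patient_id = pid, day = as.integer(day), system = system,
      code = code, value = as.numeric(value))
    invisible(NULL)
  }

  # demographics at the start of care; birth date carried by the event date
  add(p$patient_id, p$birth_day, "DEMOG", "birth_date")
  add(p$patient_id, p$care_start_day, "DEMOG",
      ifelse(p$sexM == 1L, "sex:M", "sex:F"))
  add(p$patient_id, p$care_start_day, "DEMOG", paste0("race:", p$race))
  add(p$patient_id, p$care_start_day, "DEMOG",
      ifelse(p$hispanic == 1L, "ethnicity:hispanic", "ethnicity:nonhispanic"))
  add(p$patient_id, p$care_start_day, "DEMOG",
      ifelse(p$rural == 1L, "residence:rural", "residence:urban"))

  # diagnoses: T2D for everyone, prior HF for some
  add(p$patient_id, p$t2d_day, "DIAG", "250.2")
  phf <- p[prior_hf == 1L]
  if (nrow(phf))
    add(phf$patient_id,
        phf$care_start_day +
          round(runif(nrow(phf)) * pmax(1, phf$index_day - 30L - phf$care_start_day)),
        "DIAG", "428")

  # medications: metformin pair, second-line pair, optional switch pair,
  # optional pre-index SGLT2i pair
  add(p$patient_id, p$m0_day, "MED", "metformin")
  add(p$patient_id, p$m0_day + p$met_gap, "MED", "metformin")
  add(p$patient_id, p$index_day, "MED", p$arm_ingredient)
  add(p$patient_id, p$index_day + p$arm_gap, "MED", p$arm_ingredient)
  sw <- p[switch == 1L]
  if (nrow(sw)) {
    add(sw$patient_id, sw$switch_day, "MED", sw$switch_ingredient)
    add(sw$patient_id, sw$switch_day + sw$switch_gap, "MED", sw$switch_ingredient)
  }
  sg <- p[prior_sglt2i == 1L]
  if (nrow(sg)) {
    d1 <- pmax(sg$care_start_day, sg$index_day - 500L - round(runif(nrow(sg), 0, 200)))
    add(sg$patient_id, d1, "MED", "empagliflozin")
    add(sg$patient_id, d1 + sample(30:180, nrow(sg), replace = TRUE),
        "MED", "empagliflozin")
  }

  # baseline labs and BMI: one measurement at the drawn "nearest" value, with
  # occasional decoys (an earlier in-window and an out-of-window measurement)
  lab_codes <- default_lab_codes()
  lab_cols <- c(hba1c = "hba1c", ldl = "ldl", hdl = "hdl",
                total_cholesterol = "total_cholesterol")
  for (lab in names(lab_cols)) {
    val <- p[[lab_cols[[lab]]]]
    has <- which(!is.na(val))
    if (!length(has)) next
    near_off <- sample(1:120, length(has), replace = TRUE)
    add(p$patient_id[has], p$index_day[has] - near_off, "LAB",
        lab_codes[[lab]], val[has])
    # an earlier, farther measurement inside the window for ~40%
    dec <- has[runif(length(has)) < 0.4]
    if (length(dec)) {
      off2 <- sample(180:364, length(dec), replace = TRUE)
      add(p$patient_id[dec], p$index_day[dec] - off2, "LAB",
          lab_codes[[lab]], rnorm(length(dec), mean(val[has]), sd(val[has]) + 1e-9))
    }
    # a stale pre-window measurement for ~30% of everyone
    old <- which(runif(n) < 0.3)
    if (length(old))
      add(p$patient_id[old], p$index_day[old] - 366L -
            sample(0:300, length(old), replace = TRUE), "LAB",
          lab_codes[[lab]], rnorm(length(old), 100, 20))
  }
  hb <- which(!is.na(p$bmi))
  if (length(hb))
    add(p$patient_id[hb], p$index_day[hb] - sample(1:364, length(hb), TRUE),
        "DEMOG", "BMI", p$bmi[hb])

  # dictionary code counts in their temporal windows
  cnt <- melt(cbind(p[, .(patient_id, index_day, care_start_day)],
                    p[, feats$label, with = FALSE]),
              id.vars = c("patient_id", "index_day", "care_start_day"),
              variable.name = "label", value.name = "count",
              variable.factor = FALSE)
  cnt <- cnt[count > 0]
  if (nrow(cnt)) {
    cnt <- cnt[feats, on = "label", nomatch = NULL]
    long <- cnt[rep(seq_len(.N), count)]
    rec <- long$window == "recent"
    off <- integer(nrow(long))
    off[rec] <- sample(1:365, sum(rec), replace = TRUE)
    if (any(!rec)) {
      span <- long$index_day[!rec] - long$care_start_day[!rec]
      off[!rec] <- 366L + floor(runif(sum(!rec)) * pmax(1, span - 365L))
    }
    add(long$patient_id, long$index_day - off, long$system, long$code)
  }

  # encounters: uniform over [care_start, w], plus guaranteed first and last
  span <- p$w_day - p$care_start_day
  n_enc <- rpois(n, cfg$encounter_rate * span / DAYS_PER_YEAR)
  tot <- sum(n_enc)
  if (tot) {
    pid <- rep(p$patient_id, n_enc)
    lo <- rep(p$care_start_day, n_enc)
    hi <- rep(p$w_day, n_enc)
    add(pid, lo + floor(runif(tot) * (hi - lo + 1L)), "ENCOUNTER", "visit")
  }
  add(p$patient_id, p$care_start_day, "ENCOUNTER", "visit")
  add(p$patient_id, p$w_day, "ENCOUNTER", "visit")

  # observed outcomes
  hf_obs <- p[event_is_hf == TRUE & hf_day <= w_day]
  if (nrow(hf_obs)) add(hf_obs$patient_id, hf_obs$hf_day, "HF_HOSP", "hf_hosp")
  de <- p[is.finite(death_day) & death_day <= cens_day]
  if (nrow(de)) add(de$patient_id, de$death_day, "DEATH", "death")

  out <- rbindlist(ev)
  out[, date := day_to_date(day)]
  setorder(out, patient_id, day, system, code)
  out[, .(patient_id, date, system, code, value)]
}

#' Generate a synthetic coded EHR event stream with known ground truth
#'
#' Draws a population from the configured world (see [sim_config()]) and
#' renders it as a long coded event stream -- demographics, diagnoses,
#' medications (metformin and second-line pairs satisfying the 30-180 day
#' pairing rule), labs, dictionary code counts in two pre-index windows,
#' encounters, HF hospitalizations and deaths. The same draws are returned in
#' tabular form as per-patient bookkeeping, and the true marginal estimands
#' are computed by Monte-Carlo integration (see [oracle_estimands()]).
#'
#' @param config a [sim_config()].
#' @param compute_truth compute the Monte-Carlo oracle (set `FALSE` to skip).
#' @param n_mc Monte-Carlo draws for the oracle.
#' @return a list with `events` (a `data.table` of coded events), `truth`
#'   (a `ground_truth` object or `NULL`), `patients` (generator
#'   bookkeeping), and `config`.
#' @export
generate_population <- function(config, compute_truth = TRUE, n_mc = 1e5) {
  validate_sim_config(config)
  set.seed(config$seed)
  sim <- simulate_cohort_draw(config)
  events <- render_events(sim)
  truth <- if (compute_truth) oracle_estimands(config, n_mc = n_mc) else NULL
  list(events = events, truth = truth, patients = sim$patients,
       config = config)
}

#' Monte-Carlo oracle for the true marginal estimands
#'
#' Computes the true 5-year risk difference and event-free survival ratio of
#' the configured world by averaging the closed-form conditional survival
#' `exp(-(lambda0 + theta*a + beta'x + death_hazard) * tau)` over fresh
#' draws of the covariate-generating distribution, with both arms evaluated
#' on the same covariate draws. The competing death hazard is part of the
#' composite event, so it enters the conditional survival; it cancels from
#' the survival ratio when `beta = 0`.
#'
#' @param config a [sim_config()].
#' @param n_mc number of Monte-Carlo covariate draws (default 1e5).
#' @param seed RNG seed for the oracle draws (default `config$seed + 1`).
#' @return an object of class `ground_truth`: `true_risk_difference`,
#'   `true_survival_ratio`, `true_theta`, `true_propensity_coefficients`,
#'   arm-specific risks, and Monte-Carlo standard errors `mc_se`.
#' @export
oracle_estimands <- function(config, n_mc = 1e5, seed = NULL) {
  validate_sim_config(config)
  if (n_mc < 1) stop_ehrdr("n_mc must be positive")
  set.seed(seed %||% (config$seed + 1L))
  feats <- sim_feature_table(config)
  tau_y <- config$tau / DAYS_PER_YEAR
  X <- draw_counts(as.integer(n_mc), config)
  bx <- as.numeric(X %*% config$confounder_effect_on_hazard)
  s_arm <- function(a) exp(-(config$baseline_hazard + config$treatment_effect * a +
                               bx + config$death_hazard) * tau_y)
  S1 <- s_arm(1); S0 <- s_arm(0)
  m1 <- mean(S1); m0 <- mean(S0)
  rd <- mean((1 - S1) - (1 - S0))
  sr <- m1 / m0
  se_rd <- sd(S0 - S1) / sqrt(n_mc)
  # delta method for log(SR) on common draws
  v1 <- var(S1) / n_mc; v0 <- var(S0) / n_mc
  cv <- cov(S1, S0) / n_mc
  # clamp: with beta = 0 the two arms' survivals are perfectly correlated
  # and the log-ratio MC variance is exactly zero up to floating error
  se_log_sr <- sqrt(max(0, v1 / m1^2 + v0 / m0^2 - 2 * cv / (m1 * m0)))
  alpha <- config$confounder_effect_on_treatment
  alpha0 <- logit(config$treated_share) - sum(alpha * feats$mu)
  out <- list(
    true_risk_difference = rd,
    true_survival_ratio = sr,
    true_risk = c(arm1 = 1 - m1, arm0 = 1 - m0),
    true_survival = c(arm1 = m1, arm0 = m0),
    true_theta = config$treatment_effect,
    true_propensity_coefficients = c(intercept = alpha0,
                                     setNames(alpha, feats$label),
                                     config$demog_effect_on_treatment),
    mc_se = list(risk_difference = se_rd,
                 survival_ratio = sr * se_log_sr,
                 log_survival_ratio = se_log_sr),
    n_mc = n_mc, tau = config$tau
  )
  class(out) <- "ground_truth"
  stopifnot(out$true_survival_ratio > 0, abs(out$true_risk_difference) <= 1)
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth (Monte-Carlo oracle, n_mc =", format(x$n_mc, big.mark = ","), ")\n")
  cat(sprintf("  true risk difference at tau: %.5f (MC SE %.2g)\n",
              x$true_risk_difference, x$mc_se$risk_difference))
  cat(sprintf("  true survival ratio at tau:  %.5f (MC SE %.2g)\n",
              x$true_survival_ratio, x$mc_se$survival_ratio))
  invisible(x)
}

#' Cohort-shaped view of the generator bookkeeping (fast path)
#'
#' Converts the per-patient truth table of [simulate_cohort_data()] /
#' [generate_population()] into the column layout produced by
#' [build_cohort()], keeping eligible patients only. Together with
#' [bookkeeping_covariates()] this is the tabular fast path used by
#' simulation studies that exercise the estimator rather than the cohort
#' builder; their agreement with the event-stream path is asserted in the
#' test suite.
#'
#' @param patients bookkeeping table.
#' @param tau horizon in days.
#' @return a cohort `data.table`.
#' @export
bookkeeping_cohort <- function(patients, tau = 1826L) {
  p <- as.data.table(patients)[eligible == TRUE]
  p[, .(patient_id, index_date = day_to_date(index_day), group = arm_class,
        arm = A, follow_days = T_days, event = delta,
        censored_at_last_encounter = delta == 0L, y_tau, status_known,
        switch = switch == 1L, tau = as.integer(tau))]
}

#' Covariate matrix from the generator bookkeeping (fast path)
#'
#' Age, sex and the dictionary count columns, aligned to
#' [bookkeeping_cohort()] rows.
#'
#' @param patients bookkeeping table.
#' @param features feature table from [simulate_cohort_data()] (or a
#'   `sim_config` to derive it).
#' @param drop optional feature labels to omit (used to misspecify a
#'   nuisance model by hiding a true confounder).
#' @return numeric matrix.
#' @export
bookkeeping_covariates <- function(patients, features, drop = NULL) {
  if (inherits(features, "sim_config")) features <- sim_feature_table(features)
  p <- as.data.table(patients)[eligible == TRUE]
  lab <- setdiff(features$label, drop)
  X <- cbind(age = p$age, sex_M = as.numeric(p$sexM),
             as.matrix(p[, lab, with = FALSE]))
  rownames(X) <- p$patient_id
  X
}
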