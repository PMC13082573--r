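#' Default lab code map (LOINC-style)
#'
#' Codes under which the four expert baseline laboratory tests are expected
#' in the LAB stream.
#'
#' @return named list: `hba1c`, `ldl`, `hdl`, `total_cholesterol`.
#' @export
default_lab_codes <- function() {
  list(hba1c = "4548-4", ldl = "13457-7", hdl = "2085-9",
       total_cholesterol = "2093-3")
}

#' Specification of the baseline covariate assembly
#'
#' Describes the expert-selected variables (with the codes they are read
#' from), the feature dictionary to count in the two pre-index temporal
#' windows, and the prevalence filter.
#'
#' Window conventions: the recent window is `[index - 365, index)` (closed
#' left, open right) and the history window is everything strictly before
#' `index - 365`; events on the index date itself are never counted, so the
#' two windows partition pre-index time.
#'
#' @param feature_dictionary data.frame with `system`, `code`, `label`
#'   (see [read_feature_dictionary()]); may have zero rows.
#' @param prevalence_threshold proportion in (0,1]; a windowed count column
#'   is retained iff at least `ceiling(threshold * n)` patients have a
#'   nonzero count (0 disables the filter).
#' @param window_days boundary between recent and history windows (days).
#' @param t2d_code,hf_code DIAG codes for T2D (duration) and HF (prior-HF
#'   flag).
#' @param lab_codes named list of LAB codes, see [default_lab_codes()].
#' @param bmi_code DEMOG code carrying BMI measurements.
#' @param sglt2i_codes MED ingredient codes defining prior SGLT2i use.
#' @param race_reference reference level of the race one-hot encoding.
#' @param log1p_counts transform windowed counts by `log(1 + count)`.
#' @param include_expert include the expert variable block.
#' @return an object of class `covariate_spec`.
#' @export
covariate_spec <- function(feature_dictionary = default_feature_dictionary(),
                           prevalence_threshold = 0.05,
                           window_days = 365L,
                           t2d_code = "250.2",
                           hf_code = "428",
                           lab_codes = default_lab_codes(),
                           bmi_code = "BMI",
                           sglt2i_codes = default_drug_classes()$SGLT2i,
                           race_reference = "white",
                           log1p_counts = FALSE,
                           include_expert = TRUE) {
  if (prevalence_threshold < 0 || prevalence_threshold >= 1)
    stop_ehrdr("prevalence_threshold must be in [0, 1)")
  spec <- list(dictionary = as.data.table(feature_dictionary),
               prevalence_threshold = prevalence_threshold,
               window_days = as.integer(window_days),
               t2d_code = t2d_code, hf_code = hf_code,
               lab_codes = lab_codes, bmi_code = bmi_code,
               sglt2i_codes = sglt2i_codes,
               race_reference = race_reference,
               log1p_counts = isTRUE(log1p_counts),
               include_expert = isTRUE(include_expert))
  class(spec) <- "covariate_spec"
  spec
}

#' Smallest patient count satisfying the prevalence rule
#'
#' @param threshold prevalence proportion.
#' @param n cohort size.
#' @return `ceiling(threshold * n)` as an integer (47 for 5% of 939).
#' @export
min_prevalence_count <- function(threshold, n) as.integer(ceiling(threshold * n))

#' Retain windowed count columns by cohort prevalence
#'
#' A count column is retained iff the number of patients with a nonzero
#' count is at least [min_prevalence_count()]; a zero threshold retains
#' everything. Raising the threshold never adds columns.
#'
#' @param counts numeric matrix of per-patient counts.
#' @param threshold prevalence proportion.
#' @return list with `X` (retained columns), `kept`, `dropped`.
#' @export
prevalence_filter <- function(counts, threshold = 0.05) {
  counts <- as.matrix(counts)
  if (threshold <= 0 || !ncol(counts))
    return(list(X = counts, kept = colnames(counts), dropped = character(0)))
  need <- min_prevalence_count(threshold, nrow(counts))
  present <- colSums(counts > 0)
  keep <- present >= need
  list(X = counts[, keep, drop = FALSE],
       kept = colnames(counts)[keep],
       dropped = colnames(counts)[!keep])
}

#' Mean-impute missing entries of a design matrix
#'
#' Each missing numeric entry is replaced by the mean of the column's
#' non-missing entries, computed on the pooled cohort (both arms). The
#' pre-imputation missingness mask is returned for diagnostics. A column
#' with no complete case is a hard error.
#'
#' @param X numeric matrix (may contain `NA`).
#' @return list with `X` (complete), `mask` (logical matrix of original
#'   missingness).
#' @export
impute_missing <- function(X) {
  X <- as.matrix(X)
  mask <- is.na(X)
  if (any(mask)) {
    allmiss <- colSums(!mask) == 0L
    if (any(allmiss))
      stop_ehrdr("column(s) entirely missing, cannot impute: ",
                 paste(colnames(X)[allmiss], collapse = ", "))
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(mask, arr.ind = TRUE)
    X[idx] <- mu[idx[, 2L]]
  }
  list(X = X, mask = mask)
}

# nearest-within-window retrieval: among events of (system, code) dated in
# [index - window, index), pick the value closest to index; equidistant ties
# go to the later-entered row (stable input order), logged.
nearest_value <- function(ev, sys, cd, idx, window = 365L) {
  cand <- ev[system == sys & code == cd]
  if (!nrow(cand)) return(NA_real_)
  d <- as.integer(cand$date)
  inwin <- d >= idx - window & d < idx
  if (!any(inwin)) return(NA_real_)
  cand <- cand[inwin]; d <- d[inwin]
  dist <- idx - d
  best <- which(dist == min(dist))
  if (length(best) > 1L)
    ehrdr_note("equidistant measurements for ", sys, ":", cd,
               "; keeping the later-entered one")
  cand$value[best[length(best)]]  # later-entered wins among ties
}

#' Assemble the expert covariate row for one patient
#'
#' Labs and BMI are retrieved within a year before index (nearest
#' measurement wins, missing if none); durations are
#' `(index - first relevant code date) / 365.25` years; prior-HF and
#' prior-SGLT2i are any-pre-index-occurrence flags; sex, race, ethnicity and
#' residence are one-hot encoded against configured reference levels.
#' Missingness is data here, not an error.
#'
#' @param events one patient's coded events.
#' @param index_date assigned index date.
#' @param spec a [covariate_spec()].
#' @param metformin_initiation optional metformin episode initiation date
#'   (for the metformin-duration variable).
#' @return named numeric vector with `NA` for missing entries.
#' @export
assemble_expert_covariates <- function(events, index_date, spec,
                                       metformin_initiation = NULL) {
  ev <- validate_events(events)
  idx <- as.integer(as.IDate(index_date))
  w <- spec$window_days
  bd <- ev[system == "DEMOG" & code == "birth_date", as.integer(date)]
  age <- if (length(bd)) (idx - min(bd)) / DAYS_PER_YEAR else NA_real_
  dem <- ev[system == "DEMOG", code]
  onehot <- function(prefix, level) {
    lv <- sub(paste0("^", prefix, ":"), "", grep(paste0("^", prefix, ":"), dem, value = TRUE))
    if (!length(lv)) return(NA_real_)
    as.numeric(lv[1] == level)
  }
  races <- c("black", "asian", "other", "white")
  race_cols <- setdiff(races, spec$race_reference)
  race_vec <- vapply(race_cols, function(r) onehot("race", r), 0)
  t2d <- ev[system == "DIAG" & code == spec$t2d_code & as.integer(date) < idx,
            as.integer(date)]
  met_dur <- if (!is.null(metformin_initiation) && !is.na(metformin_initiation))
    (idx - as.integer(as.IDate(metformin_initiation))) / DAYS_PER_YEAR else NA_real_
  labs <- vapply(names(spec$lab_codes), function(nm)
    nearest_value(ev, "LAB", spec$lab_codes[[nm]], idx, w), 0)
  out <- c(
    age = age,
    sex_M = onehot("sex", "M"),
    setNames(race_vec, paste0("race_", race_cols)),
    ethnicity_hispanic = onehot("ethnicity", "hispanic"),
    residence_rural = onehot("residence", "rural"),
    bmi = nearest_value(ev, "DEMOG", spec$bmi_code, idx, w),
    t2d_duration = if (length(t2d)) (idx - min(t2d)) / DAYS_PER_YEAR else NA_real_,
    metformin_duration = met_dur,
    prior_hf = as.numeric(nrow(ev[system == "DIAG" & code == spec$hf_code &
                                    as.integer(date) < idx]) > 0),
    prior_sglt2i = as.numeric(nrow(ev[system == "MED" & code %in% spec$sglt2i_codes &
                                        as.integer(date) < idx]) > 0),
    labs
  )
  out
}

#' Count dictionary features in the two pre-index windows for one patient
#'
#' For each dictionary key the history count is the number of matching
#' events dated strictly before `index - 365` and the recent count the
#' number dated in `[index - 365, index)`; index-day events count in
#' neither.
#'
#' @param events one patient's coded events.
#' @param index_date assigned index date.
#' @param spec a [covariate_spec()] with a non-empty dictionary.
#' @return named integer vector, `<label>_hist` then `<label>_recent`.
#' @export
count_window_features <- function(events, index_date, spec) {
  if (!nrow(spec$dictionary)) stop_ehrdr("empty feature dictionary")
  ev <- validate_events(events)
  idx <- as.integer(as.IDate(index_date))
  w <- spec$window_days
  m <- ev[spec$dictionary, on = c("system", "code"), nomatch = NULL]
  d <- as.integer(m$date)
  lab <- m$label
  hist_ct <- table(factor(lab[d < idx - w], levels = spec$dictionary$label))
  rec_ct <- table(factor(lab[d >= idx - w & d < idx], levels = spec$dictionary$label))
  c(setNames(as.integer(hist_ct), paste0(spec$dictionary$label, "_hist")),
    setNames(as.integer(rec_ct), paste0(spec$dictionary$label, "_recent")))
}

#' Build the baseline covariate matrix for a cohort
#'
#' Vectorized assembly of the expert block (nearest-within-year labs/BMI,
#' durations, flags, one-hot demographics, pooled mean imputation) and the
#' two-window dictionary counts with the prevalence filter applied over the
#' final eligible cohort.
#'
#' @param events coded event table covering the cohort.
#' @param cohort cohort table from [build_cohort()].
#' @param spec a [covariate_spec()].
#' @param episodes optional episode table (for metformin duration); detected
#'   from `events` if omitted.
#' @return list of class `covariate_matrix`: `X` (numeric matrix, rows
#'   aligned to `cohort`), `mask` (expert-block missingness before
#'   imputation), `provenance` (named `expert` / `history_window` /
#'   `recent_window`), `dropped` (count columns removed by the prevalence
#'   filter), `spec`.
#' @export
build_covariate_matrix <- function(events, cohort, spec = covariate_spec(),
                                   episodes = NULL) {
  ev <- validate_events(events)
  coh <- as.data.table(cohort)
  if (!nrow(coh)) stop_ehrdr("empty cohort")
  if (is.null(episodes)) episodes <- detect_medication_episodes(ev)
  met <- as.data.table(episodes)[class == "metformin",
                                 .(met_init = min(as.integer(initiation_date))),
                                 by = patient_id]
  key <- coh[, .(patient_id, idx = as.integer(as.IDate(index_date)))]
  ev <- ev[patient_id %in% key$patient_id]
  ev[, day := as.integer(date)]
  evk <- key[ev, on = "patient_id", nomatch = NULL]

  expert <- NULL
  mask <- NULL
  if (spec$include_expert) {
    # demographics
    bd <- evk[system == "DEMOG" & code == "birth_date",
              .(age = (idx[1] - min(day)) / DAYS_PER_YEAR), by = patient_id]
    dem <- evk[system == "DEMOG" & grepl(":", code, fixed = TRUE)]
    dem[, c("field", "level") := tstrsplit(code, ":", fixed = TRUE)]
    dem <- unique(dem[, .(patient_id, field, level)], by = c("patient_id", "field"))
    demw <- dcast(dem, patient_id ~ field, value.var = "level")
    for (f in c("sex", "race", "ethnicity", "residence"))
      if (!f %in% names(demw)) demw[, (f) := NA_character_]

    # nearest-in-window labs / BMI: max day wins, later input row breaks ties
    lab_map <- rbindlist(lapply(names(spec$lab_codes), function(nm)
      data.table(system = "LAB", code = spec$lab_codes[[nm]], var = nm)))
    lab_map <- rbind(lab_map,
                     data.table(system = "DEMOG", code = spec$bmi_code, var = "bmi"))
    lv <- evk[lab_map, on = c("system", "code"), nomatch = NULL]
    lv <- lv[day >= idx - spec$window_days & day < idx]
    lv[, rowid := .I]
    setorder(lv, patient_id, var, day, rowid)
    lv <- lv[, .SD[.N], by = .(patient_id, var)]
    labw <- dcast(lv, patient_id ~ var, value.var = "value")
    for (v in c(names(spec$lab_codes), "bmi"))
      if (!v %in% names(labw)) labw[, (v) := NA_real_]

    t2d <- evk[system == "DIAG" & code == spec$t2d_code & day < idx,
               .(t2d_duration = (idx[1] - min(day)) / DAYS_PER_YEAR), by = patient_id]
    phf <- evk[system == "DIAG" & code == spec$hf_code & day < idx,
               .(prior_hf = 1), by = patient_id]
    psg <- evk[system == "MED" & code %in% spec$sglt2i_codes & day < idx,
               .(prior_sglt2i = 1), by = patient_id]

    e <- key
    for (tb in list(bd, demw, labw, t2d, phf, psg, met))
      e <- tb[e, on = "patient_id"]
    e[, metformin_duration := fifelse(!is.na(met_init), (idx - met_init) / DAYS_PER_YEAR,
                                      NA_real_)]
    race_cols <- setdiff(c("black", "asian", "other", "white"), spec$race_reference)
    setorder(e, patient_id)
    e <- e[key$patient_id, on = "patient_id"]  # align to cohort order
    expert <- cbind(
      age = e$age,
      sex_M = ifelse(is.na(e$sex), NA_real_, as.numeric(e$sex == "M")),
      vapply(race_cols, function(r)
        ifelse(is.na(e$race), NA_real_, as.numeric(e$race == r)),
        numeric(nrow(e))),
      ethnicity_hispanic = ifelse(is.na(e$ethnicity), NA_real_,
                                  as.numeric(e$ethnicity == "hispanic")),
      residence_rural = ifelse(is.na(e$residence), NA_real_,
                               as.numeric(e$residence == "rural")),
      bmi = e$bmi,
      t2d_duration = e$t2d_duration,
      metformin_duration = e$metformin_duration,
      prior_hf = fifelse(is.na(e$prior_hf), 0, 1),
      prior_sglt2i = fifelse(is.na(e$prior_sglt2i), 0, 1),
      vapply(names(spec$lab_codes), function(v) e[[v]], numeric(nrow(e)))
    )
    colnames(expert)[3:(2 + length(race_cols))] <- paste0("race_", race_cols)
    imp <- impute_missing(expert)
    expert <- imp$X
    mask <- imp$mask
    rownames(expert) <- key$patient_id
  }

  # windowed counts
  counts <- NULL
  dropped <- character(0)
  if (nrow(spec$dictionary)) {
    mt <- evk[spec$dictionary, on = c("system", "code"), nomatch = NULL]
    mt <- mt[day < idx]
    mt[, win := fifelse(day >= idx - spec$window_days, "recent", "hist")]
    ct <- mt[, .N, by = .(patient_id, label, win)]
    labels <- spec$dictionary$label
    allcols <- c(paste0(labels, "_hist"), paste0(labels, "_recent"))
    if (nrow(ct)) {
      ct[, col := paste0(label, "_", win)]
      cw <- dcast(ct, patient_id ~ col, value.var = "N", fill = 0L)
      cw <- cw[key$patient_id, on = "patient_id"]
      counts <- matrix(0, nrow(key), length(allcols),
                       dimnames = list(key$patient_id, allcols))
      for (cl in setdiff(names(cw), "patient_id"))
        counts[, cl] <- fifelse(is.na(cw[[cl]]), 0L, cw[[cl]])
    } else {
      counts <- matrix(0, nrow(key), length(allcols),
                       dimnames = list(key$patient_id, allcols))
    }
    flt <- prevalence_filter(counts, spec$prevalence_threshold)
    counts <- flt$X
    dropped <- flt$dropped
    if (spec$log1p_counts) counts <- log1p(counts)
  }

  X <- cbind(expert, counts)
  prov <- c(if (!is.null(expert)) setNames(rep("expert", ncol(expert)), colnames(expert)),
            if (!is.null(counts))
              setNames(fifelse(grepl("_hist$", colnames(counts)),
                               "history_window", "recent_window"),
                       colnames(counts)))
  structure(list(X = X, mask = mask, provenance = prov, dropped = dropped,
                 spec = spec),
            class = "covariate_matrix")
}

#' @export
print.covariate_matrix <- function(x, ...) {
  tb <- table(x$provenance)
  cat("Covariate matrix:", nrow(x$X), "patients x", ncol(x$X), "columns (",
      paste(names(tb), tb, sep = "=", collapse = ", "), ")\n")
  if (length(x$dropped))
    cat("  prevalence filter dropped", length(x$dropped), "count columns\n")
  invisible(x)
}
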