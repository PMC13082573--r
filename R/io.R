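#' Read a coded event stream from CSV
#'
#' The event-stream dialect is UTF-8 CSV with header
#' `patient_id,date,system,code,value`; `date` is ISO-8601 (YYYY-MM-DD),
#' `system` one of `r paste(EVENT_SYSTEMS, collapse = ", ")`, and `value`
#' empty when inapplicable. Dates are validated against a plausible calendar
#' range (1900--2040).
#'
#' @param path path to the CSV file.
#' @return a `data.table` of coded events with `date` parsed to `IDate`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop_ehrdr("event file not found: ", path)
  ev <- fread(path, colClasses = list(character = c("patient_id", "system", "code")))
  validate_events(ev)
}

#' Validate a coded event table
#'
#' Checks required columns, parseable in-range dates and known systems;
#' repeated `(patient_id, date, system, code)` rows are allowed and
#' meaningful (they are counted downstream).
#'
#' @param events a data.frame/data.table of events.
#' @return the validated events as a `data.table` (invisibly usable).
#' @export
validate_events <- function(events) {
  ev <- if (is.data.table(events)) copy(events) else as.data.table(events)
  need <- c("patient_id", "date", "system", "code")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop_ehrdr("event stream lacks column(s): ", paste(miss, collapse = ", "))
  if (!"value" %in% names(ev)) ev[, value := NA_real_]
  ev[, date := as.IDate(date)]
  if (anyNA(ev$date)) stop_ehrdr("unparseable event dates")
  if (any(ev$date < EHRDR_DATE_MIN | ev$date > EHRDR_DATE_MAX))
    stop_ehrdr("event dates outside the plausible range ",
               EHRDR_DATE_MIN, "..", EHRDR_DATE_MAX)
  bad <- setdiff(unique(ev$system), EVENT_SYSTEMS)
  if (length(bad))
    stop_ehrdr("unknown event system(s): ", paste(bad, collapse = ", "))
  ev[, value := as.numeric(value)]
  ev[]
}

#' Write a coded event stream to CSV
#'
#' @param events event table (see [read_events()] for the dialect).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  ev <- as.data.table(events)[, .(patient_id, date = as.IDate(date), system, code, value)]
  fwrite(ev, path)
  invisible(path)
}

#' Read / write a drug-class map as YAML
#'
#' The YAML layout is `classes: {insulin: [codes...], sulfonylureas: [...]}`.
#' Ingredient codes must be disjoint across classes.
#'
#' @param path YAML file path.
#' @return a named list of character vectors (class -> ingredient codes).
#' @export
read_drug_classes <- function(path) {
  if (!file.exists(path)) stop_ehrdr("drug class map not found: ", path)
  y <- read_yaml(path)
  classes <- y$classes %||% y
  classes <- lapply(classes, as.character)
  validate_drug_classes(classes)
}

#' @rdname read_drug_classes
#' @param classes named list of ingredient-code vectors.
#' @export
write_drug_classes <- function(classes, path) {
  validate_drug_classes(classes)
  write_yaml(list(classes = lapply(classes, as.list)), path)
  invisible(path)
}

validate_drug_classes <- function(classes) {
  if (is.null(names(classes)) || any(names(classes) == ""))
    stop_ehrdr("drug class map must be a named list")
  codes <- unlist(classes, use.names = FALSE)
  if (anyDuplicated(codes))
    stop_ehrdr("ingredient codes must be disjoint across classes: ",
               paste(unique(codes[duplicated(codes)]), collapse = ", "))
  classes
}

#' Read a feature dictionary from YAML
#'
#' A list of `{system, code, label}` entries naming the rolled-up codes whose
#' pre-index occurrences are counted in the two temporal windows.
#'
#' @param path YAML file path.
#' @return a `data.table` with columns `system`, `code`, `label`.
#' @export
read_feature_dictionary <- function(path) {
  if (!file.exists(path)) stop_ehrdr("feature dictionary not found: ", path)
  y <- read_yaml(path)
  entries <- y$features %||% y
  dict <- rbindlist(lapply(entries, function(e)
    data.table(system = e$system, code = as.character(e$code),
               label = e$label %||% paste0(e$system, ":", e$code))))
  if (!nrow(dict)) stop_ehrdr("empty feature dictionary: ", path)
  dict
}

#' @rdname read_feature_dictionary
#' @param dictionary a data.frame with `system`, `code`, `label`.
#' @export
write_feature_dictionary <- function(dictionary, path) {
  d <- as.data.table(dictionary)
  write_yaml(list(features = lapply(seq_len(nrow(d)), function(i)
    list(system = d$system[i], code = d$code[i], label = d$label[i]))), path)
  invisible(path)
}

#' Serialize a simulation configuration to / from YAML
#'
#' @param config a [sim_config()].
#' @param path YAML file path.
#' @return `path` (write) or a `sim_config` (read).
#' @export
write_sim_config <- function(config, path) {
  validate_sim_config(config)
  write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop_ehrdr("sim config not found: ", path)
  y <- read_yaml(path)
  y$demog_effect_on_treatment <- unlist(y$demog_effect_on_treatment)
  do.call(sim_config, y)
}

#' Serialize ground truth to JSON
#'
#' @param truth a `ground_truth` object from [oracle_estimands()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
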