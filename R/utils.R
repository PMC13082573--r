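# Calendar anchor: day 0 of all integer day offsets used internally.
EHRDR_EPOCH <- as.Date("2010-01-01")

# Plausible calendar range for event dates; anything outside is rejected at
# parse time (birth dates can reach back a century).
EHRDR_DATE_MIN <- as.Date("1900-01-01")
EHRDR_DATE_MAX <- as.Date("2040-12-31")

DAYS_PER_YEAR <- 365.25

EVENT_SYSTEMS <- c("DIAG", "MED", "LAB", "PROC", "NOTE_CUI", "ENCOUNTER",
                   "DEMOG", "DEATH", "HF_HOSP")

INTERVENTION_CLASSES <- c("insulin", "sulfonylureas", "DPP4i", "GLP1RA")

#' Convert integer day offsets to calendar dates
#'
#' Day 0 is anchored at 2010-01-01; all internal interval arithmetic is in
#' whole days.
#'
#' @param day integer vector of day offsets.
#' @return a `Date` vector.
#' @export
day_to_date <- function(day) EHRDR_EPOCH + as.integer(round(day))

#' Convert calendar dates to integer day offsets
#'
#' @param date a `Date` (or coercible) vector.
#' @return integer day offsets from the package epoch (2010-01-01).
#' @export
date_to_day <- function(date) as.integer(as.Date(date) - EHRDR_EPOCH)

expit <- function(x) plogis(x)
logit <- function(p) qlogis(p)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Diagnostic chatter (tie-breaks, clipping, ignored codes) is routed through
# here so simulations stay quiet unless options(ehrdr.verbose = TRUE).
ehrdr_note <- function(...) {
  if (isTRUE(getOption("ehrdr.verbose", FALSE))) message("[ehrdr] ", ...)
  invisible(NULL)
}

stop_ehrdr <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == round(x)
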