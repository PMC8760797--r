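# Domain model for ICU encounters, event streams and daily expert ratings.

#' Working diagnosis categories
#'
#' The five ordinal working-diagnosis categories of the daily bedside
#' questionnaire, in increasing presumed severity. Codes 1--5 are used
#' throughout; codes >= 3 form the sepsis spectrum.
#'
#' @format character vector of length 5.
#' @export
WD_LEVELS <- c("neither", "SIRS", "sepsis", "severe_sepsis", "septic_shock")

#' Smallest ordinal code in the sepsis spectrum (sepsis = 3).
#' @export
SEPSIS_CODE <- 3L

#' Convert working-diagnosis labels to ordinal codes and back
#'
#' @param label character vector of labels among [WD_LEVELS] (NA allowed).
#' @param code integer vector of codes 1--5 (NA allowed).
#' @return `wd_code` returns integer codes; `wd_label` returns labels.
#' @examples
#' wd_code("septic_shock")
#' wd_label(1:5)
#' @export
wd_code <- function(label) {
  out <- match(label, WD_LEVELS)
  bad <- !is.na(label) & is.na(out)
  if (any(bad)) {
    stop("unknown working diagnosis label(s): ",
         paste(unique(label[bad]), collapse = ", "))
  }
  as.integer(out)
}

#' @rdname wd_code
#' @export
wd_label <- function(code) WD_LEVELS[as.integer(code)]

#' Derive encounter start and end
#'
#' The encounter start is the earlier of the administrative admission time and
#' the first charted vital sign; the end is the later of the administrative
#' discharge time and the last charted vital sign. Either vital-sign time may
#' be absent, in which case the administrative time stands alone.
#'
#' @param pdms_admission admission timestamp from the patient data management
#'   system (may be `NA` when only vital-sign times exist).
#' @param his_discharge discharge timestamp from the hospital information
#'   system (may be `NA`).
#' @param first_vital,last_vital first/last vital-sign charting times, or `NA`.
#' @return list with POSIXct elements `start` and `end`, `start <= end`.
#' @examples
#' derive_encounter_bounds(as.POSIXct("2017-01-01 10:00", tz = "UTC"),
#'                         as.POSIXct("2017-01-01 18:00", tz = "UTC"),
#'                         as.POSIXct("2017-01-01 09:30", tz = "UTC"),
#'                         as.POSIXct("2017-01-01 18:20", tz = "UTC"))
#' @export
derive_encounter_bounds <- function(pdms_admission, his_discharge,
                                    first_vital = NA, last_vital = NA) {
  starts <- c(as.numeric(.as_ts(pdms_admission)), as.numeric(.as_ts(first_vital)))
  ends <- c(as.numeric(.as_ts(his_discharge)), as.numeric(.as_ts(last_vital)))
  starts <- starts[!is.na(starts)]
  ends <- ends[!is.na(ends)]
  if (length(starts) == 0L || length(ends) == 0L) {
    stop("invalid encounter: no start or no end candidate available")
  }
  if (!is.na(pdms_admission) && !is.na(his_discharge) &&
      as.numeric(.as_ts(pdms_admission)) > as.numeric(.as_ts(his_discharge))) {
    stop("invalid encounter: admission after discharge")
  }
  start <- min(starts)
  end <- max(ends)
  if (start > end) stop("invalid encounter: derived start after derived end")
  list(start = .POSIXct(start, tz = "UTC"), end = .POSIXct(end, tz = "UTC"))
}

#' Daily rating schedule of an encounter
#'
#' All daily rating instants (default 14:00 local) contained in
#' `[start, end]`, ascending. Empty when the encounter spans no such instant.
#'
#' @param start,end encounter bounds (POSIXct).
#' @param rating_hour hour of day of the rating anchor (default 14).
#' @return POSIXct vector (possibly length 0).
#' @examples
#' s <- as.POSIXct("2017-01-01 09:00", tz = "UTC")
#' e <- as.POSIXct("2017-01-03 16:00", tz = "UTC")
#' rating_schedule(s, e)
#' @export
rating_schedule <- function(start, end, rating_hour = 14) {
  start <- .as_ts(start); end <- .as_ts(end)
  if (as.numeric(start) > as.numeric(end)) stop("start after end")
  day0 <- as.numeric(start) - (as.numeric(start) %% 86400)
  first <- day0 + rating_hour * 3600
  if (first < as.numeric(start)) first <- first + 86400
  if (first > as.numeric(end)) return(.POSIXct(numeric(0), tz = "UTC"))
  .POSIXct(seq(first, as.numeric(end), by = 86400), tz = "UTC")
}

#' Editing rate over a rating schedule
#'
#' Fraction of schedule instants at which at least one edited questionnaire
#' record exists. A record is "edited" when it carries at least one reply to
#' the content items (the `edited` flag of the record); a record present
#' without such a reply does not count.
#'
#' @param records data frame with columns `rating_time` (POSIXct) and
#'   `edited` (logical).
#' @param schedule POSIXct vector of rating instants (non-empty).
#' @return fraction in `[0, 1]`.
#' @export
editing_rate <- function(records, schedule) {
  if (length(schedule) == 0L) {
    stop("editing rate undefined: empty rating schedule")
  }
  edited_at <- unique(as.numeric(records$rating_time[records$edited %in% TRUE]))
  mean(as.numeric(schedule) %in% edited_at)
}

# ---- cohort container ------------------------------------------------------

#' Observation variables understood by the criteria engine
#'
#' Vital signs, laboratory values and therapy markers that feed SIRS and SOFA
#' evaluation. Vasopressors are carried as one variable per agent
#' (dose in ug/kg/min); `ventilated` is 0/1.
#' @export
OBS_VARIABLES <- c(
  "temperature", "heart_rate", "resp_rate", "paco2", "wbc", "band_fraction",
  "pao2_fio2", "platelets", "bilirubin", "map",
  "norepinephrine", "epinephrine", "dopamine", "dobutamine",
  "ventilated", "gcs", "creatinine", "urine_output_24h"
)

ORDER_KINDS <- c("antibiotic_administration", "body_fluid_culture")
REFERRAL_GROUPS <- c("neurosurgical", "non_neurosurgical", "unknown")

#' Assemble a cohort object
#'
#' Bundles the four event tables (validated with [validate_cohort()]) into a
#' `sepsis_cohort` list. Column contracts:
#' \describe{
#'   \item{encounters}{`encounter_id`, `pdms_admission`, `his_discharge`,
#'     `first_vital`, `last_vital`, `referral_group`, `icu_death`,
#'     `start`, `end`}
#'   \item{observations}{`encounter_id`, `time`, `variable`, `value`}
#'   \item{orders}{`encounter_id`, `time`, `kind`}
#'   \item{gtsq}{`encounter_id`, `rating_time`, `working_diagnosis`,
#'     `suspicion_of_infection`, `edited`}
#' }
#'
#' @param encounters,observations,orders,gtsq the four tables.
#' @param truth optional generator ground-truth table (synthetic cohorts).
#' @param validate run [validate_cohort()] (default TRUE).
#' @param pre_window_hours accepted pre-admission observation window.
#' @return object of class `sepsis_cohort`.
#' @export
as_cohort <- function(encounters, observations, orders, gtsq, truth = NULL,
                      validate = TRUE, pre_window_hours = 48) {
  x <- structure(
    list(encounters = encounters, observations = observations,
         orders = orders, gtsq = gtsq, truth = truth),
    class = "sepsis_cohort")
  if (validate) x <- validate_cohort(x, pre_window_hours = pre_window_hours)
  x
}

#' Validate and normalize a cohort
#'
#' Checks the column contracts of [as_cohort()], derives missing
#' `start`/`end` columns, coerces timestamps, checks categorical domains and
#' value finiteness, and drops observations earlier than the pre-admission
#' window (48 h before start by default) with a warning.
#'
#' @param cohort a `sepsis_cohort`.
#' @param pre_window_hours observations up to this many hours before the
#'   encounter start are retained; earlier ones are dropped.
#' @return the normalized cohort.
#' @export
validate_cohort <- function(cohort, pre_window_hours = 48) {
  stopifnot(inherits(cohort, "sepsis_cohort"))
  enc <- cohort$encounters
  need <- c("encounter_id", "pdms_admission", "his_discharge")
  miss <- setdiff(need, names(enc))
  if (length(miss)) stop("encounters table missing columns: ", paste(miss, collapse = ", "))
  for (col in c("pdms_admission", "his_discharge", "first_vital", "last_vital")) {
    if (col %in% names(enc)) enc[[col]] <- .as_ts(enc[[col]])
  }
  if (anyDuplicated(enc$encounter_id)) stop("duplicated encounter_id")
  if (!all(c("start", "end") %in% names(enc))) {
    fv <- if ("first_vital" %in% names(enc)) enc$first_vital else rep(NA, nrow(enc))
    lv <- if ("last_vital" %in% names(enc)) enc$last_vital else rep(NA, nrow(enc))
    b <- lapply(seq_len(nrow(enc)), function(i) {
      derive_encounter_bounds(enc$pdms_admission[i], enc$his_discharge[i], fv[i], lv[i])
    })
    enc$start <- .POSIXct(vapply(b, function(z) as.numeric(z$start), 0), tz = "UTC")
    enc$end <- .POSIXct(vapply(b, function(z) as.numeric(z$end), 0), tz = "UTC")
  } else {
    enc$start <- .as_ts(enc$start); enc$end <- .as_ts(enc$end)
  }
  if (any(as.numeric(enc$start) > as.numeric(enc$end))) stop("encounter start after end")
  if ("referral_group" %in% names(enc) &&
      !all(enc$referral_group %in% REFERRAL_GROUPS)) {
    stop("referral_group outside {", paste(REFERRAL_GROUPS, collapse = ", "), "}")
  }

  obs <- cohort$observations
  if (nrow(obs)) {
    obs$time <- .as_ts(obs$time)
    if (!all(obs$variable %in% OBS_VARIABLES)) {
      stop("unknown observation variable(s): ",
           paste(setdiff(unique(obs$variable), OBS_VARIABLES), collapse = ", "))
    }
    if (!all(is.finite(obs$value))) stop("non-finite observation values")
    bounds <- enc[match(obs$encounter_id, enc$encounter_id), c("start", "end")]
    if (anyNA(bounds$start)) stop("observations reference unknown encounter_id")
    lo <- as.numeric(bounds$start) - pre_window_hours * 3600
    hi <- as.numeric(bounds$end)
    keep <- as.numeric(obs$time) >= lo & as.numeric(obs$time) <= hi
    if (any(!keep)) {
      warning(sum(!keep), " observation(s) outside [start - ",
              pre_window_hours, " h, end] dropped")
      obs <- obs[keep, , drop = FALSE]
      rownames(obs) <- NULL
    }
  }

  ord <- cohort$orders
  if (nrow(ord)) {
    ord$time <- .as_ts(ord$time)
    if (!all(ord$kind %in% ORDER_KINDS)) {
      stop("order kind outside {", paste(ORDER_KINDS, collapse = ", "), "}")
    }
  }

  gtsq <- cohort$gtsq
  if (nrow(gtsq)) {
    gtsq$rating_time <- .as_ts(gtsq$rating_time)
    wd <- gtsq$working_diagnosis
    if (!all(is.na(wd) | wd %in% WD_LEVELS)) {
      stop("working_diagnosis outside the five categories")
    }
    if (!"edited" %in% names(gtsq)) gtsq$edited <- !is.na(wd)
  }

  cohort$encounters <- enc
  cohort$observations <- obs
  cohort$orders <- ord
  cohort$gtsq <- gtsq
  cohort
}

#' @export
print.sepsis_cohort <- function(x, ...) {
  cat("<sepsis_cohort> ", nrow(x$encounters), " encounters, ",
      nrow(x$observations), " observations, ", nrow(x$orders), " orders, ",
      nrow(x$gtsq), " ratings\n", sep = "")
  invisible(x)
}

.TS_FMT <- "%Y-%m-%dT%H:%M:%S"

.write_ts_csv <- function(df, path) {
  for (col in names(df)) {
    if (inherits(df[[col]], "POSIXct")) {
      df[[col]] <- format(df[[col]], .TS_FMT, tz = "UTC")
    }
  }
  utils::write.csv(df, path, row.names = FALSE)
}

.read_ts_csv <- function(path, ts_cols) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(ts_cols, names(df))) {
    df[[col]] <- as.POSIXct(df[[col]], tz = "UTC", format = .TS_FMT)
  }
  df
}

#' Write / read a cohort as CSV tables
#'
#' Round-trip writer for the four tables (`encounters.csv`,
#' `observations.csv`, `orders.csv`, `gtsq.csv`) with ISO-8601 timestamps;
#' a synthetic cohort additionally gets `truth.csv`. The required columns are
#' described by the JSON schema shipped in `inst/extdata/cohort_schema.json`.
#'
#' @param cohort a `sepsis_cohort`.
#' @param dir directory (created if needed).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` a validated
#'   `sepsis_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sepsis_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_ts_csv(cohort$encounters, file.path(dir, "encounters.csv"))
  .write_ts_csv(cohort$observations, file.path(dir, "observations.csv"))
  .write_ts_csv(cohort$orders, file.path(dir, "orders.csv"))
  .write_ts_csv(cohort$gtsq, file.path(dir, "gtsq.csv"))
  if (!is.null(cohort$truth)) .write_ts_csv(cohort$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  ts_enc <- c("pdms_admission", "his_discharge", "first_vital", "last_vital",
              "start", "end")
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) {
    .read_ts_csv(truth_path, c("first_sepsis_time", "t_suspicion",
                               "sirs_from", "sirs_until"))
  }
  as_cohort(
    encounters = .read_ts_csv(file.path(dir, "encounters.csv"), ts_enc),
    observations = .read_ts_csv(file.path(dir, "observations.csv"), "time"),
    orders = .read_ts_csv(file.path(dir, "orders.csv"), "time"),
    gtsq = .read_ts_csv(file.path(dir, "gtsq.csv"), "rating_time"),
    truth = truth)
}
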