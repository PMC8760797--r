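# Processing of the daily working-diagnosis label sequences: day-2 transfer,
# on-admission rule, absorbing-state encounter category, incident vs
# on-admission timing, day-to-day transitions and the validation inclusion
# filter.

#' Label sequence of one encounter
#'
#' Aligns the questionnaire records of an encounter to its rating schedule
#' and returns the ordinal working-diagnosis codes (1--5, `NA` when missing
#' or unedited), one per schedule instant.
#'
#' @param gtsq records of one encounter (`rating_time`, `working_diagnosis`,
#'   `edited`).
#' @param schedule the encounter's rating schedule.
#' @return integer vector of codes aligned to `schedule`.
#' @export
label_sequence <- function(gtsq, schedule) {
  codes <- rep(NA_integer_, length(schedule))
  if (nrow(gtsq) == 0L) return(codes)
  idx <- match(as.numeric(.as_ts(gtsq$rating_time)), as.numeric(schedule))
  ok <- !is.na(idx) & (gtsq$edited %in% TRUE) & !is.na(gtsq$working_diagnosis)
  codes[idx[ok]] <- wd_code(gtsq$working_diagnosis[ok])
  codes
}

#' Day-2 label transfer
#'
#' When the day-1 label is missing and the day-2 label belongs to the sepsis
#' spectrum, the specific day-2 label is transferred to the first rating time
#' point; otherwise the sequence is unchanged. Used for the validation
#' pipeline so that on-admission sepsis documented only on day 2 still
#' anchors at day 1.
#'
#' @param codes integer label codes aligned to the schedule.
#' @return possibly modified codes.
#' @export
apply_day2_transfer <- function(codes) {
  if (length(codes) >= 2L && is.na(codes[1]) && !is.na(codes[2]) &&
      codes[2] >= SEPSIS_CODE) {
    codes[1] <- codes[2]
  }
  codes
}

#' On-admission label
#'
#' The day-1 label when present, else the day-2 label, else none (`NA`).
#'
#' @param codes integer label codes aligned to the schedule.
#' @return integer code or `NA`.
#' @export
on_admission_label <- function(codes) {
  if (length(codes) >= 1L && !is.na(codes[1])) return(codes[1])
  if (length(codes) >= 2L && !is.na(codes[2])) return(codes[2])
  NA_integer_
}

#' Encounter category (absorbing state)
#'
#' The most severe working diagnosis observed during the encounter, i.e. the
#' ordinal maximum over neither < SIRS < sepsis < severe_sepsis <
#' septic_shock.
#'
#' @param codes integer label codes (at least one non-missing).
#' @return integer code 1--5.
#' @export
encounter_category <- function(codes) {
  if (all(is.na(codes))) {
    stop("encounter uncategorized: all working diagnosis labels missing")
  }
  max(codes, na.rm = TRUE)
}

#' Classify sepsis timing of an encounter
#'
#' Partition of encounters by when the first sepsis-spectrum label appears
#' (applied after the day-2 transfer):
#' \describe{
#'   \item{sepsis_free}{no sepsis-spectrum label at all}
#'   \item{incident}{the first sepsis label is preceded by at least one
#'     non-missing non-sepsis label}
#'   \item{on_admission}{the first sepsis label is the on-admission label
#'     (day 1, or day 2 with day 1 missing) with no preceding non-sepsis
#'     label}
#'   \item{indeterminate}{first sepsis label after day 2 with only missing
#'     labels before it}
#' }
#'
#' @param codes integer label codes aligned to the schedule.
#' @param schedule the rating schedule (for `first_sepsis_time`).
#' @return list with `timing` and `first_sepsis_time` (POSIXct or `NA`).
#' @export
classify_timing <- function(codes, schedule) {
  stopifnot(length(codes) == length(schedule))
  idx <- which(!is.na(codes) & codes >= SEPSIS_CODE)
  if (!length(idx)) {
    return(list(timing = "sepsis_free",
                first_sepsis_time = .POSIXct(NA_real_, tz = "UTC")))
  }
  i <- idx[1]
  before <- codes[seq_len(i - 1L)]
  timing <- if (any(!is.na(before) & before < SEPSIS_CODE)) {
    "incident"
  } else if (i <= 2L) {
    "on_admission"   # day 1, or day 2 with day 1 missing (no non-sepsis before)
  } else {
    "indeterminate"
  }
  list(timing = timing, first_sepsis_time = schedule[i])
}

#' Day-to-day label transitions
#'
#' Pairs of labels on calendar-adjacent rating instants with both labels
#' present; a missing day breaks adjacency.
#'
#' @param codes integer label codes aligned to the schedule.
#' @return data frame with integer columns `from` and `to` (0 rows when no
#'   adjacent pair is complete).
#' @export
transitions <- function(codes) {
  n <- length(codes)
  if (n < 2L) return(data.frame(from = integer(0), to = integer(0)))
  a <- codes[-n]; b <- codes[-1]
  ok <- !is.na(a) & !is.na(b)
  data.frame(from = as.integer(a[ok]), to = as.integer(b[ok]))
}

.longest_na_run <- function(codes) {
  r <- rle(is.na(codes))
  m <- r$lengths[r$values]
  if (length(m)) max(m) else 0L
}

#' Classify all encounters of a cohort
#'
#' Builds each encounter's aligned label sequence, optionally applies the
#' day-2 transfer, and derives the absorbing-state category, the timing
#' class, the first sepsis label instant and missingness summaries.
#'
#' @param cohort a `sepsis_cohort`.
#' @param day2_transfer apply [apply_day2_transfer()] (default TRUE, as the
#'   validation pipeline does; turn off for purely descriptive summaries).
#' @param rating_hour rating anchor hour.
#' @return data frame with one row per encounter: `encounter_id`, `category`
#'   (code, `NA` when all labels missing), `category_label`, `timing`,
#'   `first_sepsis_time`, `n_ratings`, `n_labels`, `longest_missing_run`,
#'   `on_admission_label`.
#' @export
classify_encounters <- function(cohort, day2_transfer = TRUE, rating_hour = 14) {
  stopifnot(inherits(cohort, "sepsis_cohort"))
  enc <- cohort$encounters
  g_by <- split(cohort$gtsq, cohort$gtsq$encounter_id)
  empty_g <- cohort$gtsq[0, ]
  n <- nrow(enc)
  na_ts <- .POSIXct(NA_real_, tz = "UTC")
  out <- data.frame(
    encounter_id = enc$encounter_id, category = NA_integer_,
    category_label = NA_character_, timing = NA_character_,
    first_sepsis_time = rep(na_ts, n), n_ratings = 0L, n_labels = 0L,
    longest_missing_run = 0L, on_admission_label = NA_integer_,
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sched <- rating_schedule(enc$start[i], enc$end[i], rating_hour)
    out$n_ratings[i] <- length(sched)
    if (!length(sched)) next
    g <- g_by[[enc$encounter_id[i]]]
    if (is.null(g)) g <- empty_g
    codes <- label_sequence(g, sched)
    if (day2_transfer) codes <- apply_day2_transfer(codes)
    out$n_labels[i] <- sum(!is.na(codes))
    out$longest_missing_run[i] <- .longest_na_run(codes)
    out$on_admission_label[i] <- on_admission_label(codes)
    if (out$n_labels[i] > 0L) {
      out$category[i] <- encounter_category(codes)
      out$category_label[i] <- wd_label(out$category[i])
    }
    tc <- classify_timing(codes, sched)
    out$timing[i] <- tc$timing
    out$first_sepsis_time[i] <- tc$first_sepsis_time
  }
  out
}

#' Validation inclusion filter
#'
#' Excludes from the criteria-validation comparison: sepsis encounters of
#' indeterminate timing, encounters without any working-diagnosis label, and
#' sepsis-free encounters whose longest run of consecutive missing labels
#' exceeds `max_missing_run` (default 2) days.
#'
#' @param classes data frame from [classify_encounters()].
#' @param max_missing_run longest tolerated run of consecutive missing labels
#'   in sepsis-free encounters.
#' @return list with `included` (subset of `classes`) and `exclusions`
#'   (data frame `encounter_id`, `reason`).
#' @export
validation_inclusion_filter <- function(classes, max_missing_run = 2) {
  reason <- rep(NA_character_, nrow(classes))
  no_labels <- classes$n_labels == 0L
  indet <- !no_labels & classes$timing == "indeterminate"
  gap <- !no_labels & classes$timing == "sepsis_free" &
    classes$longest_missing_run > max_missing_run
  reason[no_labels] <- "no_working_diagnosis_labels"
  reason[indet] <- "indeterminate_sepsis_timing"
  reason[gap] <- "sepsis_free_missing_label_run"
  excl <- !is.na(reason)
  list(included = classes[!excl, , drop = FALSE],
       exclusions = data.frame(encounter_id = classes$encounter_id[excl],
                               reason = reason[excl],
                               stringsAsFactors = FALSE))
}
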