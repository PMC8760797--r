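# Suspicion-of-infection detection, 72-h infection windows and the
# adjudication of Sepsis-1/2 and Sepsis-3 at infection onset.

#' Detect suspicion of infection from order pairing
#'
#' A qualifying pair exists when an antibiotic administration precedes a body
#' fluid culture by at most `abx_first_hours` (default 24 h), or a culture
#' precedes an antibiotic by at most `culture_first_hours` (default 72 h).
#' The suspicion time is the earlier event of the earliest qualifying pair.
#'
#' @param orders data frame with `time` (POSIXct) and `kind` in
#'   `{antibiotic_administration, body_fluid_culture}`.
#' @param abx_first_hours pairing window when the antibiotic comes first.
#' @param culture_first_hours pairing window when the culture comes first.
#' @param all return all qualifying suspicion times (ascending, unique)
#'   instead of only the earliest.
#' @return POSIXct suspicion time(s), or `NULL` when no pair qualifies.
#' @export
detect_suspicion <- function(orders, abx_first_hours = 24,
                             culture_first_hours = 72, all = FALSE) {
  if (is.null(orders) || nrow(orders) == 0L) return(NULL)
  tn <- as.numeric(.as_ts(orders$time))
  abx <- sort(tn[orders$kind == "antibiotic_administration"])
  cul <- sort(tn[orders$kind == "body_fluid_culture"])
  if (!length(abx) || !length(cul)) return(NULL)
  qual <- numeric(0)
  for (a in abx) {
    if (any(cul >= a & cul - a <= abx_first_hours * 3600)) qual <- c(qual, a)
  }
  for (cc in cul) {
    if (any(abx >= cc & abx - cc <= culture_first_hours * 3600)) qual <- c(qual, cc)
  }
  if (!length(qual)) return(NULL)
  qual <- sort(unique(qual))
  if (!all) qual <- qual[1]
  .POSIXct(qual, tz = "UTC")
}

#' Infection window around a suspicion time
#'
#' The 72-h window starting 48 h before and ending 24 h after the moment of
#' suspicion, truncated at the encounter bounds when given. Both ends are
#' closed.
#'
#' @param t_suspicion suspicion time.
#' @param enc_start,enc_end optional encounter bounds for truncation.
#' @param before_hours,after_hours window extent (defaults 48 and 24).
#' @return list with `t_suspicion`, `window_start`, `window_end`.
#' @export
infection_window <- function(t_suspicion, enc_start = NULL, enc_end = NULL,
                             before_hours = 48, after_hours = 24) {
  ts <- as.numeric(.as_ts(t_suspicion))
  ws <- ts - before_hours * 3600
  we <- ts + after_hours * 3600
  if (!is.null(enc_start)) ws <- max(ws, as.numeric(.as_ts(enc_start)))
  if (!is.null(enc_end)) we <- min(we, as.numeric(.as_ts(enc_end)))
  list(t_suspicion = .POSIXct(ts, tz = "UTC"),
       window_start = .POSIXct(ws, tz = "UTC"),
       window_end = .POSIXct(we, tz = "UTC"))
}

#' Sepsis-1/2 criteria at infection onset
#'
#' Met if SIRS is present at any grid instant of the infection window.
#'
#' @param episode as returned by [infection_window()].
#' @param series criteria series covering the window, see [criteria_series()].
#' @return logical.
#' @export
sepsis12_at_onset <- function(episode, series) {
  tn <- as.numeric(series$time)
  inw <- tn >= as.numeric(episode$window_start) &
    tn <= as.numeric(episode$window_end)
  any(series$sirs_present[inw])
}

#' Sepsis-3 criteria at infection onset
#'
#' In `absolute` mode, met if the rolling SOFA reaches 2 or more at any grid
#' instant of the window; in `delta` mode, met if it increases by 2 or more
#' over its value at the (truncated) window start.
#'
#' @inheritParams sepsis12_at_onset
#' @param mode `"absolute"` or `"delta"`.
#' @return logical.
#' @export
sepsis3_at_onset <- function(episode, series, mode = c("absolute", "delta")) {
  mode <- match.arg(mode)
  tn <- as.numeric(series$time)
  inw <- which(tn >= as.numeric(episode$window_start) &
                 tn <= as.numeric(episode$window_end))
  if (!length(inw)) return(FALSE)
  peak <- max(series$sofa[inw])
  if (mode == "absolute") return(peak >= 2)
  baseline <- series$sofa[inw[1]]
  (peak - baseline) >= 2
}

#' Adjudicate one encounter
#'
#' Detects the first suspicion of infection, builds the truncated 72-h
#' infection window, evaluates the criteria series inside it and fills the
#' three detection flags. Returns `NULL` when no suspicion qualifies; the
#' onset time of a criteria-based diagnosis is the suspicion time.
#'
#' @param encounter one-row data frame (or list) with `start`, `end`.
#' @param observations,orders event tables of this encounter.
#' @param sirs_cfg,sofa_cfg threshold tables.
#' @param abx_first_hours,culture_first_hours pairing windows, see
#'   [detect_suspicion()].
#' @return list (`InfectionEpisode`) with `t_suspicion`, `window_start`,
#'   `window_end`, `sepsis12_met`, `sepsis3_met`, `sepsis3_delta_met`,
#'   `onset_time`; or `NULL`.
#' @export
adjudicate_encounter <- function(encounter, observations, orders,
                                 sirs_cfg = sirs_thresholds(),
                                 sofa_cfg = sofa_thresholds(),
                                 abx_first_hours = 24,
                                 culture_first_hours = 72) {
  t_susp <- detect_suspicion(orders, abx_first_hours, culture_first_hours)
  if (is.null(t_susp)) return(NULL)
  ep <- infection_window(t_susp, encounter$start, encounter$end)
  series <- criteria_series(observations, ep$window_start, ep$window_end,
                            enc_start = encounter$start,
                            sirs_cfg = sirs_cfg, sofa_cfg = sofa_cfg)
  ep$sepsis12_met <- sepsis12_at_onset(ep, series)
  ep$sepsis3_met <- sepsis3_at_onset(ep, series, "absolute")
  ep$sepsis3_delta_met <- sepsis3_at_onset(ep, series, "delta")
  ep$onset_time <- ep$t_suspicion
  ep
}

#' Adjudicate a whole cohort
#'
#' One row per encounter; encounters without a qualifying suspicion get `NA`
#' times and `FALSE` flags.
#'
#' @param cohort a `sepsis_cohort`.
#' @inheritParams adjudicate_encounter
#' @return data frame with `encounter_id`, `t_suspicion`, `window_start`,
#'   `window_end`, `sepsis12_met`, `sepsis3_met`, `sepsis3_delta_met`,
#'   `onset_time`, `suspicion_found`.
#' @export
adjudicate_cohort <- function(cohort, sirs_cfg = sirs_thresholds(),
                              sofa_cfg = sofa_thresholds(),
                              abx_first_hours = 24, culture_first_hours = 72) {
  stopifnot(inherits(cohort, "sepsis_cohort"))
  enc <- cohort$encounters
  obs_by <- split(cohort$observations, cohort$observations$encounter_id)
  ord_by <- split(cohort$orders, cohort$orders$encounter_id)
  n <- nrow(enc)
  na_ts <- .POSIXct(NA_real_, tz = "UTC")
  out <- data.frame(
    encounter_id = enc$encounter_id,
    t_suspicion = rep(na_ts, n), window_start = rep(na_ts, n),
    window_end = rep(na_ts, n),
    sepsis12_met = FALSE, sepsis3_met = FALSE, sepsis3_delta_met = FALSE,
    onset_time = rep(na_ts, n), suspicion_found = FALSE,
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    id <- enc$encounter_id[i]
    ep <- adjudicate_encounter(
      enc[i, ],
      if (is.null(obs_by[[id]])) cohort$observations[0, ] else obs_by[[id]],
      if (is.null(ord_by[[id]])) cohort$orders[0, ] else ord_by[[id]],
      sirs_cfg, sofa_cfg, abx_first_hours, culture_first_hours)
    if (is.null(ep)) next
    out$t_suspicion[i] <- ep$t_suspicion
    out$window_start[i] <- ep$window_start
    out$window_end[i] <- ep$window_end
    out$sepsis12_met[i] <- ep$sepsis12_met
    out$sepsis3_met[i] <- ep$sepsis3_met
    out$sepsis3_delta_met[i] <- ep$sepsis3_delta_met
    out$onset_time[i] <- ep$onset_time
    out$suspicion_found[i] <- TRUE
  }
  out
}
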