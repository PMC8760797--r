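# SIRS point determination and rolling 24-h SOFA on a carry-forward state.
#
# Patient state is reconstructed as a right-continuous step function: every
# charted value is carried forward until replaced. SIRS is a point
# determination on the current state; each SOFA subscore is the maximum of
# its pointwise value over the preceding 24 h (truncated at encounter start),
# and the total is the sum of the six subscore maxima.

#' Default SIRS criterion thresholds
#'
#' The four classic criteria: temperature > 38 or < 36 deg C; heart rate
#' > 90/min; respiratory rate > 20/min or PaCO2 < 32 mmHg; WBC > 12 or
#' < 4 x 10^3/mm^3 or band forms > 10%.
#'
#' @return named list of cut-offs.
#' @export
sirs_thresholds <- function() {
  list(temp_high = 38, temp_low = 36, hr = 90, rr = 20, paco2 = 32,
       wbc_high = 12, wbc_low = 4, bands = 10)
}

#' Default SOFA subscore cut-offs
#'
#' The original subscore table: respiration by PaO2/FiO2 (400/300/200/100,
#' scores 3-4 requiring ventilatory support; with ventilation status unknown
#' the subscore is capped at 2), platelets 150/100/50/20, bilirubin
#' 1.2/2.0/6.0/12.0 mg/dL, cardiovascular by MAP < 70 mmHg and vasopressor
#' dose tiers, GCS 13-14/10-12/6-9/<6, creatinine 1.2/2.0/3.5/5.0 mg/dL or
#' 24-h urine output < 500 / < 200 mL.
#'
#' @return nested named list of cut-offs.
#' @export
sofa_thresholds <- function() {
  list(
    pao2_fio2 = c(400, 300, 200, 100),
    platelets = c(150, 100, 50, 20),
    bilirubin = c(1.2, 2.0, 6.0, 12.0),
    map_low = 70,
    dopamine = c(5, 15),        # <=5 -> 2; >5 -> 3; >15 -> 4
    epi_norepi = 0.1,           # <=0.1 -> 3; >0.1 -> 4
    gcs = c(15, 13, 10, 6),     # 15 -> 0; 13-14 -> 1; 10-12 -> 2; 6-9 -> 3; <6 -> 4
    creatinine = c(1.2, 2.0, 3.5, 5.0),
    urine = c(500, 200)
  )
}

#' Load threshold tables from JSON
#'
#' Reads a SIRS or SOFA threshold table from a JSON file; the package ships
#' its defaults under `inst/extdata/sirs.json` and `inst/extdata/sofa.json`,
#' which are read when `path` is omitted.
#'
#' @param which `"sirs"` or `"sofa"`.
#' @param path optional path to a user JSON file with the same keys.
#' @return named list usable as `sirs_cfg` / `sofa_cfg`.
#' @export
load_criteria_config <- function(which = c("sirs", "sofa"), path = NULL) {
  which <- match.arg(which)
  if (is.null(path)) {
    path <- system.file("extdata", paste0(which, ".json"),
                        package = "sepsiscriteria")
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$description <- NULL
  ref <- if (which == "sirs") sirs_thresholds() else sofa_thresholds()
  miss <- setdiff(names(ref), names(cfg))
  if (length(miss)) stop("threshold table missing keys: ", paste(miss, collapse = ", "))
  cfg[names(ref)]
}

#' Evaluation grid over an interval
#'
#' Timestamps at which the criteria are (re-)evaluated: every event time in
#' `[start, end]` plus fill instants so that no gap exceeds `max_gap_min`
#' minutes; `start` and `end` are always included.
#'
#' @param event_times POSIXct event times (any order, outside times ignored).
#' @param start,end interval bounds.
#' @param max_gap_min maximal allowed gap in minutes (default 30).
#' @return ascending POSIXct vector.
#' @export
evaluation_grid <- function(event_times, start, end, max_gap_min = 30) {
  s <- as.numeric(.as_ts(start)); e <- as.numeric(.as_ts(end))
  if (s > e) stop("start after end")
  gap <- max_gap_min * 60
  ev <- sort(unique(as.numeric(.as_ts(event_times))))
  ev <- ev[ev >= s & ev <= e]
  anchors <- unique(c(s, ev, e))
  out <- numeric(0)
  for (i in seq_len(length(anchors) - 1L)) {
    a <- anchors[i]; b <- anchors[i + 1L]
    out <- c(out, a)
    if (b - a > gap) {
      fills <- seq(a + gap, b, by = gap)
      out <- c(out, fills[fills < b])
    }
  }
  out <- unique(c(out, e))
  .POSIXct(out, tz = "UTC")
}

#' Carry-forward state at a time point
#'
#' Per variable, the most recent observed value at or before `t`; variables
#' without any prior observation are absent. When two entries share a
#' timestamp, the later row in input order wins.
#'
#' @param observations data frame with `time`, `variable`, `value`.
#' @param t query time.
#' @return named numeric vector (possibly empty).
#' @export
carry_forward_state <- function(observations, t) {
  tn <- as.numeric(.as_ts(observations$time))
  keep <- which(tn <= as.numeric(.as_ts(t)))
  if (!length(keep)) return(stats::setNames(numeric(0), character(0)))
  sub <- observations[keep, , drop = FALSE]
  ord <- order(as.numeric(.as_ts(sub$time)))  # stable: ties keep input order
  sub <- sub[ord, , drop = FALSE]
  idx <- split(seq_len(nrow(sub)), sub$variable)
  vapply(idx, function(i) sub$value[i[length(i)]], numeric(1))
}

#' SIRS point determination
#'
#' Number of SIRS criteria met by a state snapshot; absent variables count as
#' not met; SIRS is present when two or more criteria are met concomitantly.
#'
#' @param state named numeric vector as from [carry_forward_state()].
#' @param thresholds cut-offs, see [sirs_thresholds()].
#' @return list with integer `count` (0--4) and logical `present`.
#' @export
sirs_point <- function(state, thresholds = sirs_thresholds()) {
  g <- function(v) if (v %in% names(state)) state[[v]] else NA_real_
  th <- thresholds
  met <- c(
    isTRUE(g("temperature") > th$temp_high) || isTRUE(g("temperature") < th$temp_low),
    isTRUE(g("heart_rate") > th$hr),
    isTRUE(g("resp_rate") > th$rr) || isTRUE(g("paco2") < th$paco2),
    isTRUE(g("wbc") > th$wbc_high) || isTRUE(g("wbc") < th$wbc_low) ||
      isTRUE(g("band_fraction") > th$bands)
  )
  count <- sum(met)
  list(count = as.integer(count), present = count >= 2L)
}

SOFA_SYSTEMS <- c("respiration", "coagulation", "liver", "cardiovascular",
                  "cns", "renal")

# Pointwise SOFA subscores of a state snapshot (missing data score 0).
.sofa_subscores_state <- function(state, cfg = sofa_thresholds()) {
  g <- function(v) if (v %in% names(state)) state[[v]] else NA_real_

  pf <- g("pao2_fio2")
  vent <- isTRUE(g("ventilated") >= 1)
  resp <- if (is.na(pf)) 0L else if (pf < cfg$pao2_fio2[4] && vent) 4L else
    if (pf < cfg$pao2_fio2[3] && vent) 3L else
    if (pf < cfg$pao2_fio2[3]) 2L else        # ventilation unknown: capped
    if (pf < cfg$pao2_fio2[2]) 2L else
    if (pf < cfg$pao2_fio2[1]) 1L else 0L

  plt <- g("platelets")
  coag <- if (is.na(plt)) 0L else if (plt < cfg$platelets[4]) 4L else
    if (plt < cfg$platelets[3]) 3L else if (plt < cfg$platelets[2]) 2L else
    if (plt < cfg$platelets[1]) 1L else 0L

  bili <- g("bilirubin")
  liver <- if (is.na(bili)) 0L else if (bili >= cfg$bilirubin[4]) 4L else
    if (bili >= cfg$bilirubin[3]) 3L else if (bili >= cfg$bilirubin[2]) 2L else
    if (bili >= cfg$bilirubin[1]) 1L else 0L

  dop <- g("dopamine"); dob <- g("dobutamine")
  epi <- g("epinephrine"); nor <- g("norepinephrine")
  map <- g("map")
  cardio <- if (isTRUE(dop > cfg$dopamine[2]) || isTRUE(epi > cfg$epi_norepi) ||
                isTRUE(nor > cfg$epi_norepi)) 4L else
    if (isTRUE(dop > cfg$dopamine[1]) ||
        (isTRUE(epi > 0) && isTRUE(epi <= cfg$epi_norepi)) ||
        (isTRUE(nor > 0) && isTRUE(nor <= cfg$epi_norepi))) 3L else
    if (isTRUE(dop > 0) || isTRUE(dob > 0)) 2L else
    if (isTRUE(map < cfg$map_low)) 1L else 0L

  gcs <- g("gcs")
  cns <- if (is.na(gcs)) 0L else if (gcs < cfg$gcs[4]) 4L else
    if (gcs < cfg$gcs[3]) 3L else if (gcs < cfg$gcs[2]) 2L else
    if (gcs < cfg$gcs[1]) 1L else 0L

  crea <- g("creatinine")
  renal_c <- if (is.na(crea)) 0L else if (crea >= cfg$creatinine[4]) 4L else
    if (crea >= cfg$creatinine[3]) 3L else if (crea >= cfg$creatinine[2]) 2L else
    if (crea >= cfg$creatinine[1]) 1L else 0L
  uo <- g("urine_output_24h")
  renal_u <- if (is.na(uo)) 0L else if (uo < cfg$urine[2]) 4L else
    if (uo < cfg$urine[1]) 3L else 0L

  stats::setNames(c(resp, coag, liver, cardio, cns, max(renal_c, renal_u)),
                  SOFA_SYSTEMS)
}

# Step table of the pointwise criteria: one row per distinct observation time
# <= `upto`, holding the SIRS count and six SOFA subscores of the state from
# that instant on. Row 0 (no observations yet) is implicitly all-absent.
.state_steps <- function(observations, upto, sirs_cfg = sirs_thresholds(),
                         sofa_cfg = sofa_thresholds()) {
  tn <- as.numeric(.as_ts(observations$time))
  keep <- which(tn <= as.numeric(.as_ts(upto)))
  sub <- observations[keep, , drop = FALSE]
  tn <- tn[keep]
  ord <- order(tn)  # stable
  sub <- sub[ord, , drop = FALSE]
  tn <- tn[ord]
  times <- unique(tn)
  k <- length(times)
  sirs <- integer(k)
  subs <- matrix(0L, nrow = k, ncol = 6, dimnames = list(NULL, SOFA_SYSTEMS))
  state <- new.env(parent = emptyenv())
  j <- 1L
  for (i in seq_len(k)) {
    while (j <= nrow(sub) && tn[j] == times[i]) {
      assign(sub$variable[j], sub$value[j], envir = state)
      j <- j + 1L
    }
    st <- unlist(as.list(state))
    if (is.null(st)) st <- numeric(0)
    sirs[i] <- sirs_point(st, sirs_cfg)$count
    subs[i, ] <- .sofa_subscores_state(st, sofa_cfg)
  }
  list(times = times, sirs = sirs, subs = subs)
}

# Rolling per-subscore maximum over (left, t], including the subscore value
# active at `left` (the step extends past it).
.rolling_sofa_from_steps <- function(steps, t, left) {
  i1 <- findInterval(left, steps$times)  # row active at left (0 = all absent)
  i2 <- findInterval(as.numeric(t), steps$times)
  if (i2 < 1L) {
    return(list(total = 0L, subscores = stats::setNames(integer(6), SOFA_SYSTEMS)))
  }
  rows <- max(i1, 1L):i2
  sub <- steps$subs[rows, , drop = FALSE]
  if (i1 == 0L) sub <- rbind(rep(0L, 6), sub)
  mx <- apply(sub, 2, max)
  list(total = as.integer(sum(mx)),
       subscores = stats::setNames(as.integer(mx), SOFA_SYSTEMS))
}

#' Rolling 24-h SOFA score
#'
#' Each of the six subscores is the maximum of its pointwise (carry-forward)
#' value over `(max(t - window, enc_start), t]`; the total is their sum. With
#' no observations at all the score is 0.
#'
#' @param observations data frame with `time`, `variable`, `value`.
#' @param t evaluation time.
#' @param window_hours rolling window length (default 24).
#' @param enc_start optional encounter start; the window is truncated there.
#' @param cfg subscore cut-offs, see [sofa_thresholds()].
#' @return list with integer `total` (0--24) and named integer `subscores`.
#' @export
sofa_rolling <- function(observations, t, window_hours = 24, enc_start = NULL,
                         cfg = sofa_thresholds()) {
  tnum <- as.numeric(.as_ts(t))
  left <- tnum - window_hours * 3600
  if (!is.null(enc_start)) left <- max(left, as.numeric(.as_ts(enc_start)))
  steps <- .state_steps(observations, t, sofa_cfg = cfg)
  .rolling_sofa_from_steps(steps, tnum, left)
}

#' SOFA at a rating instant
#'
#' The rolling 24-h SOFA evaluated at a 2 PM rating time, used for
#' on-admission (first rating instant) and maximum-SOFA summaries.
#'
#' @inheritParams sofa_rolling
#' @param rating_time the rating instant.
#' @return integer total score.
#' @export
sofa_at_rating <- function(observations, rating_time, enc_start = NULL,
                           window_hours = 24, cfg = sofa_thresholds()) {
  sofa_rolling(observations, rating_time, window_hours = window_hours,
               enc_start = enc_start, cfg = cfg)$total
}

#' Criteria series over an interval
#'
#' Evaluates the SIRS point determination and the rolling 24-h SOFA on the
#' evaluation grid of `[start, end]` (every event time plus 30-min fill
#' instants).
#'
#' @param observations data frame with `time`, `variable`, `value` (may
#'   include events before `start`; they initialize the carried state).
#' @param start,end interval to evaluate.
#' @param enc_start encounter start for window truncation (default `start`).
#' @param max_gap_min grid fill interval in minutes.
#' @param window_hours SOFA rolling window.
#' @param sirs_cfg,sofa_cfg threshold tables.
#' @return data frame with `time`, `sirs_count`, `sirs_present`, `sofa` and
#'   the six subscore columns.
#' @export
criteria_series <- function(observations, start, end, enc_start = start,
                            max_gap_min = 30, window_hours = 24,
                            sirs_cfg = sirs_thresholds(),
                            sofa_cfg = sofa_thresholds()) {
  grid <- evaluation_grid(observations$time, start, end, max_gap_min)
  steps <- .state_steps(observations, end, sirs_cfg, sofa_cfg)
  gnum <- as.numeric(grid)
  enc0 <- as.numeric(.as_ts(enc_start))
  sirs_idx <- findInterval(gnum, steps$times)
  sirs_count <- ifelse(sirs_idx >= 1L, steps$sirs[pmax(sirs_idx, 1L)], 0L)
  res <- matrix(0L, nrow = length(grid), ncol = 7,
                dimnames = list(NULL, c("sofa", SOFA_SYSTEMS)))
  for (i in seq_along(gnum)) {
    left <- max(gnum[i] - window_hours * 3600, enc0)
    r <- .rolling_sofa_from_steps(steps, gnum[i], left)
    res[i, ] <- c(r$total, r$subscores)
  }
  out <- data.frame(time = grid, sirs_count = as.integer(sirs_count),
                    sirs_present = sirs_count >= 2L)
  cbind(out, as.data.frame(res))
}
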