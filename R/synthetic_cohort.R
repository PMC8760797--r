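# Synthetic ICU cohort generator. Emulates the statistical structure the
# analysis assumes -- encounter bounds with vital-sign margins, daily ordinal
# working-diagnosis chains with configurable self-transition, planted
# antibiotic/culture order pairs and threshold-crossing observations tied to
# a configurable detection model -- so every downstream stage is testable
# without patient data. It does not attempt physiological realism.

#' Default rater confusion matrix
#'
#' Row-stochastic 5x5 matrix for replicate raters: 0.92 on the diagonal with
#' the remainder split over ordinally adjacent categories, emulating high
#' ordinal interrater agreement with rare, small-magnitude disagreements.
#'
#' @return 5x5 matrix with rows summing to 1.
#' @export
default_rater_confusion <- function() {
  k <- 5
  m <- matrix(0, k, k)
  for (i in seq_len(k)) {
    nb <- intersect(c(i - 1, i + 1), seq_len(k))
    m[i, i] <- 0.92
    m[i, nb] <- 0.08 / length(nb)
  }
  m
}

#' Synthetic cohort configuration
#'
#' All probabilities of the generative model with defaults mirroring the
#' structure of a one-year interdisciplinary surgical ICU survey: 42.6%
#' sepsis-label prevalence, a 2:1 on-admission to incident sepsis ratio, 83%
#' day-to-day label self-transition, 1.6% missing daily labels, category mix
#' and lengths of stay per eventual working-diagnosis category, and a planted
#' criteria-detection model (sensitivity/specificity of the clinical criteria
#' against the label, plus the probability that a detected onset falls within
#' the 24 h before the first label).
#'
#' @param n_encounters number of encounters (>= 1).
#' @param seed master RNG seed; per-encounter substreams derive from it.
#' @param p_sepsis_label probability of any sepsis-spectrum label.
#' @param p_on_admission_given_sepsis probability that a sepsis encounter is
#'   on-admission rather than incident.
#' @param label_self_transition day-to-day probability of keeping the label.
#' @param sepsis_category_probs mix of the three sepsis categories.
#' @param nonsepsis_category_probs mix of neither vs SIRS.
#' @param mean_length_days mean encounter length per eventual category.
#' @param icu_mortality ICU death probability per eventual category.
#' @param criteria_sensitivity planted P(criteria met | sepsis label).
#' @param criteria_specificity planted P(criteria absent | no sepsis label).
#' @param p_timely_given_detected probability that a detected criteria onset
#'   falls within the 24 h before the first sepsis label.
#' @param observation_cadence_hours background charting cadence.
#' @param p_missing_label daily rate of missing working diagnoses on edited
#'   questionnaires.
#' @param p_edited probability that a scheduled questionnaire is edited.
#' @param p_neurosurgical share of neurosurgical referrals.
#' @param rater_confusion 5x5 row-stochastic confusion matrix for replicate
#'   raters.
#' @param study_start anchor timestamp of the survey period.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_encounters = 200, seed = 1,
                          p_sepsis_label = 0.426,
                          p_on_admission_given_sepsis = 2 / 3,
                          label_self_transition = 0.83,
                          sepsis_category_probs = c(sepsis = 51, severe_sepsis = 34,
                                                    septic_shock = 247) / 332,
                          nonsepsis_category_probs = c(neither = 312, SIRS = 113) / 425,
                          mean_length_days = c(neither = 3.1, SIRS = 5.6, sepsis = 9.3,
                                               severe_sepsis = 11.8, septic_shock = 17.2),
                          icu_mortality = c(neither = 0.064, SIRS = 0.195, sepsis = 0.059,
                                            severe_sepsis = 0.059, septic_shock = 0.397),
                          criteria_sensitivity = 0.85,
                          criteria_specificity = 0.90,
                          p_timely_given_detected = 0.90,
                          observation_cadence_hours = 4,
                          p_missing_label = 0.016,
                          p_edited = 0.921,
                          p_neurosurgical = 0.478,
                          rater_confusion = default_rater_confusion(),
                          study_start = "2016-07-18 00:00:00") {
  cfg <- list(
    n_encounters = n_encounters, seed = seed, p_sepsis_label = p_sepsis_label,
    p_on_admission_given_sepsis = p_on_admission_given_sepsis,
    label_self_transition = label_self_transition,
    sepsis_category_probs = sepsis_category_probs,
    nonsepsis_category_probs = nonsepsis_category_probs,
    mean_length_days = mean_length_days, icu_mortality = icu_mortality,
    criteria_sensitivity = criteria_sensitivity,
    criteria_specificity = criteria_specificity,
    p_timely_given_detected = p_timely_given_detected,
    observation_cadence_hours = observation_cadence_hours,
    p_missing_label = p_missing_label, p_edited = p_edited,
    p_neurosurgical = p_neurosurgical, rater_confusion = rater_confusion,
    study_start = .as_ts(study_start))
  probs <- c("p_sepsis_label", "p_on_admission_given_sepsis",
             "label_self_transition", "criteria_sensitivity",
             "criteria_specificity", "p_timely_given_detected",
             "p_missing_label", "p_edited", "p_neurosurgical")
  bad <- character(0)
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) bad <- c(bad, p)
  }
  if (!is.numeric(n_encounters) || n_encounters < 1) bad <- c(bad, "n_encounters")
  if (abs(sum(sepsis_category_probs) - 1) > 1e-8) bad <- c(bad, "sepsis_category_probs")
  if (abs(sum(nonsepsis_category_probs) - 1) > 1e-8) bad <- c(bad, "nonsepsis_category_probs")
  if (any(mean_length_days <= 0)) bad <- c(bad, "mean_length_days")
  if (any(icu_mortality < 0 | icu_mortality > 1)) bad <- c(bad, "icu_mortality")
  rc <- rater_confusion
  if (!is.matrix(rc) || any(dim(rc) != 5) || any(rc < 0) ||
      any(abs(rowSums(rc) - 1) > 1e-8)) bad <- c(bad, "rater_confusion")
  if (length(bad)) {
    stop("invalid cohort configuration, offending field(s): ",
         paste(unique(bad), collapse = ", "))
  }
  structure(cfg, class = "cohort_config")
}

.resample1 <- function(x) x[sample.int(length(x), 1L)]

# Ordinal Markov chain on codes lo..hi with self-transition s; moves go to an
# adjacent code inside the range.
.markov_chain <- function(n, start, lo, hi, s) {
  out <- integer(n)
  if (n == 0L) return(out)
  out[1] <- start
  if (lo == hi) return(rep(lo, n))
  for (i in seq_len(n - 1L)) {
    cur <- out[i]
    if (runif(1) < s) {
      out[i + 1L] <- cur
    } else {
      nb <- intersect(c(cur - 1L, cur + 1L), lo:hi)
      out[i + 1L] <- .resample1(nb)
    }
  }
  out
}

# Background observation means/sds, placed well away from every SIRS and SOFA
# threshold so that undisturbed encounters score 0 almost surely.
.BG_VARS <- data.frame(
  variable = c("temperature", "heart_rate", "resp_rate", "wbc", "platelets",
               "bilirubin", "map", "gcs", "creatinine", "pao2_fio2"),
  mean = c(37.0, 78, 14, 8, 250, 0.6, 88, 15, 0.9, 470),
  sd = c(0.2, 4, 1.5, 0.8, 20, 0.1, 5, 0, 0.08, 15),
  stringsAsFactors = FALSE)

.gen_encounter <- function(i, cfg) {
  id <- sprintf("E%05d", i)
  has_sepsis <- runif(1) < cfg$p_sepsis_label
  category <- if (has_sepsis) {
    sample(3:5, 1, prob = cfg$sepsis_category_probs)
  } else {
    sample(1:2, 1, prob = cfg$nonsepsis_category_probs)
  }

  mean_len <- cfg$mean_length_days[[category]]
  dur_days <- min(1.2 + rexp(1, rate = 1 / max(mean_len - 1.2, 0.5)), 60)
  admission <- .round_minute(cfg$study_start + runif(1, 0, 330) * 86400)
  discharge <- .round_minute(admission + dur_days * 86400)
  first_vital <- .round_minute(admission + runif(1, -20, 20) * 60)
  last_vital <- .round_minute(discharge + runif(1, -20, 20) * 60)
  b <- derive_encounter_bounds(admission, discharge, first_vital, last_vital)
  sched <- rating_schedule(b$start, b$end)
  n_days <- length(sched)

  s <- cfg$label_self_transition
  onset_idx <- NA_integer_
  if (!has_sepsis) {
    codes <- if (category == 1L) rep(1L, n_days) else
      .markov_chain(n_days, 2L, 1L, 2L, s)
    timing_plan <- "sepsis_free"
  } else {
    incident <- n_days >= 2L && runif(1) >= cfg$p_on_admission_given_sepsis
    if (incident) {
      onset_idx <- .resample1(2:min(n_days, 7L))
      pre <- .markov_chain(onset_idx - 1L, .resample1(1:2), 1L, 2L, s)
      post <- .markov_chain(n_days - onset_idx + 1L, category, 3L, category, s)
      codes <- c(pre, post)
      timing_plan <- "incident"
    } else {
      onset_idx <- 1L
      codes <- .markov_chain(n_days, category, 3L, category, s)
      timing_plan <- "on_admission"
    }
  }
  first_sepsis_time <- if (has_sepsis) sched[onset_idx] else .POSIXct(NA_real_, tz = "UTC")

  edited <- runif(n_days) < cfg$p_edited
  missing <- runif(n_days) < cfg$p_missing_label
  wd <- ifelse(edited & !missing, wd_label(codes), NA_character_)
  gtsq <- data.frame(
    encounter_id = id, rating_time = sched,
    working_diagnosis = wd,
    suspicion_of_infection = ifelse(is.na(wd), NA_character_,
                                    ifelse(codes >= 3L, "yes", "no")),
    edited = edited, stringsAsFactors = FALSE)

  # background observation stream
  bg_times <- .POSIXct(seq(as.numeric(b$start),
                           as.numeric(b$end),
                           by = cfg$observation_cadence_hours * 3600), tz = "UTC")
  obs_list <- lapply(seq_len(nrow(.BG_VARS)), function(v) {
    data.frame(encounter_id = id, time = bg_times,
               variable = .BG_VARS$variable[v],
               value = round(rnorm(length(bg_times), .BG_VARS$mean[v],
                                   .BG_VARS$sd[v]), 2),
               stringsAsFactors = FALSE)
  })

  # criteria planting
  detected <- if (has_sepsis) runif(1) < cfg$criteria_sensitivity else
    runif(1) < (1 - cfg$criteria_specificity)
  t_susp <- .POSIXct(NA_real_, tz = "UTC")
  timeliness <- NA_character_
  orders <- data.frame(encounter_id = character(0), time = .POSIXct(numeric(0), tz = "UTC"),
                       kind = character(0), stringsAsFactors = FALSE)
  if (detected) {
    start_n <- as.numeric(b$start); end_n <- as.numeric(b$end)
    if (has_sepsis) {
      anchor <- as.numeric(first_sepsis_time)
      gap_h <- (anchor - start_n) / 3600
      if (runif(1) < cfg$p_timely_given_detected) {
        t_s <- anchor - runif(1, 0, min(24, gap_h)) * 3600
        timeliness <- "timely"
      } else if (gap_h > 24.5 && runif(1) < 0.5) {
        t_s <- anchor - (24 + runif(1, 0.25, min(24, gap_h - 24))) * 3600
        timeliness <- "early"
      } else if ((end_n - anchor) / 3600 > 1.5) {
        t_s <- anchor + runif(1, 1, min(24, (end_n - anchor) / 3600)) * 3600
        timeliness <- "late"
      } else {
        t_s <- anchor - runif(1, 0, min(24, gap_h)) * 3600
        timeliness <- "timely"
      }
    } else {
      t_s <- as.numeric(b$start) +
        runif(1, 0.05, 0.95) * (as.numeric(b$end) - as.numeric(b$start))
      timeliness <- "no_label"
    }
    t_susp <- .round_minute(.POSIXct(t_s, tz = "UTC"))
    culture_t <- .POSIXct(min(as.numeric(t_susp) + 2 * 3600, as.numeric(b$end)),
                          tz = "UTC")
    orders <- data.frame(
      encounter_id = id,
      time = c(t_susp, culture_t),
      kind = c("antibiotic_administration", "body_fluid_culture"),
      stringsAsFactors = FALSE)

    # SIRS + SOFA threshold crossings inside the infection window
    ep_times <- .POSIXct(pmin(as.numeric(t_susp) + c(0, 1, 3, 5) * 3600,
                              as.numeric(b$end)), tz = "UTC")
    ep_times <- .POSIXct(unique(as.numeric(ep_times)), tz = "UTC")
    crossing <- data.frame(
      encounter_id = id,
      time = rep(ep_times, times = 4),
      variable = rep(c("temperature", "heart_rate", "platelets", "creatinine"),
                     each = length(ep_times)),
      value = rep(c(39.1, 126, 45, 2.6), each = length(ep_times)),
      stringsAsFactors = FALSE)
    recov_t <- as.numeric(t_susp) + 26 * 3600
    recovery <- if (recov_t <= as.numeric(b$end)) {
      data.frame(encounter_id = id, time = .POSIXct(rep(recov_t, 4), tz = "UTC"),
                 variable = c("temperature", "heart_rate", "platelets", "creatinine"),
                 value = c(37.0, 80, 240, 0.9), stringsAsFactors = FALSE)
    } else {
      crossing[0, ]
    }
    obs_list <- c(obs_list, list(crossing, recovery))
  } else if (runif(1) < 0.15) {
    # unpaired culture: realistic noise that must not trigger suspicion
    orders <- data.frame(
      encounter_id = id,
      time = .round_minute(.POSIXct(as.numeric(b$start) +
        runif(1, 0.1, 0.9) * (as.numeric(b$end) - as.numeric(b$start)), tz = "UTC")),
      kind = "body_fluid_culture", stringsAsFactors = FALSE)
  }

  encounters <- data.frame(
    encounter_id = id, pdms_admission = admission, his_discharge = discharge,
    first_vital = first_vital, last_vital = last_vital,
    referral_group = if (runif(1) < cfg$p_neurosurgical) "neurosurgical" else "non_neurosurgical",
    icu_death = runif(1) < cfg$icu_mortality[[category]],
    start = b$start, end = b$end, stringsAsFactors = FALSE)

  truth <- data.frame(
    encounter_id = id, category = category,
    category_label = wd_label(category), timing = timing_plan,
    first_sepsis_time = first_sepsis_time, detected = detected,
    timeliness = timeliness, t_suspicion = t_susp,
    sirs_from = if (detected) t_susp else .POSIXct(NA_real_, tz = "UTC"),
    sirs_until = if (detected) .POSIXct(as.numeric(t_susp) + 5 * 3600, tz = "UTC") else
      .POSIXct(NA_real_, tz = "UTC"),
    planted_sofa_peak = if (detected) 5L else 0L,
    stringsAsFactors = FALSE)

  list(encounters = encounters, observations = do.call(rbind, obs_list),
       orders = orders, gtsq = gtsq, truth = truth)
}

#' Generate a synthetic cohort
#'
#' Draws encounters, daily label sequences (ordinal Markov chains), background
#' and planted observations, and antibiotic/culture order pairs per the
#' configured detection model. One master seed feeds a per-encounter
#' substream, so regeneration is stable encounter by encounter. For
#' label-positive encounters flagged detected (and for planted false
#' positives), a qualifying order pair plus SIRS- and SOFA-crossing
#' observations are planted inside the infection window; the criteria onset
#' is placed timely or untimely per `p_timely_given_detected`.
#'
#' @param config a [cohort_config()].
#' @return validated `sepsis_cohort` whose `truth` element records the
#'   planted ground truth per encounter.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  enc_seeds <- sample.int(.Machine$integer.max - 1L, config$n_encounters)
  parts <- vector("list", config$n_encounters)
  for (i in seq_len(config$n_encounters)) {
    set.seed(enc_seeds[i])
    parts[[i]] <- .gen_encounter(i, config)
  }
  bind <- function(f) do.call(rbind, lapply(parts, `[[`, f))
  cohort <- as_cohort(
    encounters = bind("encounters"), observations = bind("observations"),
    orders = bind("orders"), gtsq = bind("gtsq"), truth = bind("truth"))
  rownames(cohort$observations) <- NULL
  cohort
}

#' Replicate rater labels from a confusion model
#'
#' For each questionnaire record with a non-missing working diagnosis, each
#' replicate rater draws independently from the confusion row of the base
#' label. Used to exercise the interrater reliability statistics.
#'
#' @param gtsq questionnaire table (the base rater).
#' @param rater_confusion 5x5 row-stochastic matrix.
#' @param n_raters number of replicate raters (default 3).
#' @param seed RNG seed.
#' @param p_missing_cell probability that a replicate cell is missing.
#' @return integer matrix units x raters (`base` plus `rater1..n`), suitable
#'   for [krippendorff_alpha()].
#' @export
generate_rater_replicates <- function(gtsq, rater_confusion = default_rater_confusion(),
                                      n_raters = 3, seed = 1,
                                      p_missing_cell = 0) {
  if (!is.matrix(rater_confusion) || any(dim(rater_confusion) != 5) ||
      any(rater_confusion < 0) || any(abs(rowSums(rater_confusion) - 1) > 1e-8)) {
    stop("invalid cohort configuration, offending field(s): rater_confusion")
  }
  base <- wd_code(gtsq$working_diagnosis)
  base <- base[!is.na(base)]
  set.seed(seed)
  out <- matrix(NA_integer_, nrow = length(base), ncol = n_raters + 1L,
                dimnames = list(NULL, c("base", paste0("rater", seq_len(n_raters)))))
  out[, 1] <- base
  for (r in seq_len(n_raters)) {
    for (u in seq_along(base)) {
      if (p_missing_cell > 0 && runif(1) < p_missing_cell) next
      out[u, r + 1L] <- sample.int(5L, 1L, prob = rater_confusion[base[u], ])
    }
  }
  out
}
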