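# Shared fixtures and independent oracles. The oracles deliberately use
# naive enumeration so they share no code path with the implementation.

ts <- function(x) as.POSIXct(x, tz = "UTC")
hrs <- function(x) x * 3600

obs_df <- function(time, variable, value, encounter_id = "E1") {
  tt <- ts(time)
  data.frame(encounter_id = rep(encounter_id, length.out = length(tt)),
             time = tt, variable = rep(variable, length.out = length(tt)),
             value = rep(value, length.out = length(tt)),
             stringsAsFactors = FALSE)
}

orders_df <- function(time, kind, encounter_id = "E1") {
  tt <- ts(time)
  data.frame(encounter_id = rep(encounter_id, length.out = length(tt)),
             time = tt, kind = rep(kind, length.out = length(tt)),
             stringsAsFactors = FALSE)
}

# ---- Krippendorff's alpha by naive all-pairs enumeration -------------------

alpha_bruteforce <- function(m, metric = "nominal") {
  m <- as.matrix(m)
  # pairable values: units with at least two non-missing cells
  unit_vals <- lapply(seq_len(nrow(m)), function(u) m[u, !is.na(m[u, ])])
  unit_vals <- unit_vals[vapply(unit_vals, length, 0L) >= 2L]
  if (!length(unit_vals)) return(NA_real_)
  pooled <- unlist(unit_vals)
  cats <- sort(unique(pooled))
  nc <- vapply(cats, function(cc) sum(pooled == cc), 0)
  delta2 <- function(a, b) {
    if (a == b) return(0)
    if (metric == "nominal") return(1)
    ia <- which(cats == a); ib <- which(cats == b)
    lo <- min(ia, ib); hi <- max(ia, ib)
    (sum(nc[lo:hi]) - (nc[lo] + nc[hi]) / 2)^2
  }
  n <- length(pooled)
  do_sum <- 0
  for (vs in unit_vals) {
    mu <- length(vs)
    for (i in seq_len(mu)) {
      for (j in seq_len(mu)) {
        if (i != j) do_sum <- do_sum + delta2(vs[i], vs[j]) / (mu - 1)
      }
    }
  }
  de_sum <- 0
  for (a in cats) for (b in cats) if (a != b) {
    de_sum <- de_sum + nc[which(cats == a)] * nc[which(cats == b)] * delta2(a, b)
  }
  if (de_sum <= 0) return(NA_real_)
  unname(1 - (do_sum / n) / (de_sum / (n * (n - 1))))
}

random_reliability <- function(n_units, n_raters, k, p_na = 0.15) {
  m <- matrix(sample.int(k, n_units * n_raters, replace = TRUE),
              nrow = n_units)
  m[matrix(runif(length(m)) < p_na, nrow = n_units)] <- NA
  m
}

# ---- dense-grid SOFA oracle ------------------------------------------------
# Independent re-statement of the subscore table plus a 1-min brute-force
# maximum over the rolling window.

oracle_subscores <- function(state) {
  v <- function(x) if (x %in% names(state)) unname(state[[x]]) else NA
  sc <- numeric(6)
  pf <- v("pao2_fio2"); vent <- identical(v("ventilated") >= 1, TRUE)
  if (!is.na(pf)) {
    sc[1] <- if (pf < 100 && vent) 4 else if (pf < 200 && vent) 3 else
      if (pf < 300) 2 else if (pf < 400) 1 else 0
  }
  p <- v("platelets")
  if (!is.na(p)) sc[2] <- if (p < 20) 4 else if (p < 50) 3 else if (p < 100) 2 else
    if (p < 150) 1 else 0
  b <- v("bilirubin")
  if (!is.na(b)) sc[3] <- if (b >= 12) 4 else if (b >= 6) 3 else if (b >= 2) 2 else
    if (b >= 1.2) 1 else 0
  dop <- v("dopamine"); dob <- v("dobutamine")
  epi <- v("epinephrine"); nor <- v("norepinephrine"); map <- v("map")
  gt <- function(x, y) !is.na(x) && x > y
  sc[4] <- if (gt(dop, 15) || gt(epi, 0.1) || gt(nor, 0.1)) 4 else
    if (gt(dop, 5) || (gt(epi, 0) && epi <= 0.1) || (gt(nor, 0) && nor <= 0.1)) 3 else
    if (gt(dop, 0) || gt(dob, 0)) 2 else
    if (!is.na(map) && map < 70) 1 else 0
  g <- v("gcs")
  if (!is.na(g)) sc[5] <- if (g < 6) 4 else if (g < 10) 3 else if (g < 13) 2 else
    if (g < 15) 1 else 0
  cr <- v("creatinine"); uo <- v("urine_output_24h")
  rc <- if (is.na(cr)) 0 else if (cr >= 5) 4 else if (cr >= 3.5) 3 else
    if (cr >= 2) 2 else if (cr >= 1.2) 1 else 0
  ru <- if (is.na(uo)) 0 else if (uo < 200) 4 else if (uo < 500) 3 else 0
  sc[6] <- max(rc, ru)
  sc
}

oracle_state <- function(obs, t) {
  keep <- which(as.numeric(obs$time) <= as.numeric(t))
  st <- list()
  if (length(keep)) {
    sub <- obs[keep, , drop = FALSE]
    sub <- sub[order(as.numeric(sub$time)), , drop = FALSE]
    for (i in seq_len(nrow(sub))) st[[sub$variable[i]]] <- sub$value[i]
  }
  st
}

sofa_dense_oracle <- function(obs, t, window_hours = 24, enc_start = NULL) {
  tn <- as.numeric(ts(t)[1])
  left <- tn - window_hours * 3600
  if (!is.null(enc_start)) left <- max(left, as.numeric(ts(enc_start)[1]))
  minutes <- seq(left + 60, tn, by = 60)
  if (!length(minutes)) minutes <- tn
  best <- numeric(6)
  for (g in minutes) {
    sc <- oracle_subscores(oracle_state(obs, g))
    best <- pmax(best, sc)
  }
  sum(best)
}

# minute-aligned random observation streams hitting values on both sides of
# every threshold
random_stream <- function(n_events, span_hours = 72, origin = "2017-03-01 00:00:00") {
  vars <- c("temperature", "heart_rate", "resp_rate", "paco2", "wbc",
            "pao2_fio2", "platelets", "bilirubin", "map", "gcs", "creatinine",
            "dopamine", "norepinephrine", "ventilated")
  rng <- list(
    temperature = c(35, 40), heart_rate = c(60, 140), resp_rate = c(8, 35),
    paco2 = c(25, 45), wbc = c(2, 20), pao2_fio2 = c(60, 500),
    platelets = c(5, 400), bilirubin = c(0.2, 15), map = c(40, 110),
    gcs = c(3, 15), creatinine = c(0.5, 6), dopamine = c(0, 20),
    norepinephrine = c(0, 0.5), ventilated = c(0, 1))
  o <- ts(origin)
  v <- sample(vars, n_events, replace = TRUE)
  val <- vapply(v, function(x) {
    r <- rng[[x]]
    z <- runif(1, r[1], r[2])
    if (x %in% c("gcs", "ventilated")) round(z) else round(z, 1)
  }, 0)
  obs_df(o + 60 * sample.int(span_hours * 60, n_events, replace = TRUE),
         v, unname(val))
}

# compact config for fast synthetic cohorts in tests
small_config <- function(n = 60, seed = 7, ...) {
  cohort_config(n_encounters = n, seed = seed, ...)
}
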