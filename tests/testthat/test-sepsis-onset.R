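test_that("suspicion pairing follows the antibiotic-first / culture-first windows", {
  # antibiotic then culture 10 h later
  o <- orders_df(c("2017-03-01 10:00", "2017-03-01 20:00"),
                 c("antibiotic_administration", "body_fluid_culture"))
  expect_equal(detect_suspicion(o), ts("2017-03-01 10:00"))
  # culture then antibiotic 48 h later (within 72 h)
  o2 <- orders_df(c("2017-03-01 10:00", "2017-03-03 10:00"),
                  c("body_fluid_culture", "antibiotic_administration"))
  expect_equal(detect_suspicion(o2), ts("2017-03-01 10:00"))
  # antibiotic then culture 40 h later: exceeds the 24-h pairing window
  o3 <- orders_df(c("2017-03-01 10:00", "2017-03-03 02:00"),
                  c("antibiotic_administration", "body_fluid_culture"))
  expect_null(detect_suspicion(o3))
  # boundary: exactly 24 h qualifies (closed window)
  o4 <- orders_df(c("2017-03-01 10:00", "2017-03-02 10:00"),
                  c("antibiotic_administration", "body_fluid_culture"))
  expect_equal(detect_suspicion(o4), ts("2017-03-01 10:00"))
  expect_null(detect_suspicion(o[0, ]))
  expect_null(detect_suspicion(orders_df("2017-03-01 10:00", "body_fluid_culture")))
})

test_that("suspicion is invariant to orders added after the first qualifying pair", {
  o <- orders_df(c("2017-03-01 10:00", "2017-03-01 20:00"),
                 c("antibiotic_administration", "body_fluid_culture"))
  extra <- orders_df(c("2017-03-05 10:00", "2017-03-05 11:00"),
                     c("antibiotic_administration", "body_fluid_culture"))
  expect_equal(detect_suspicion(rbind(o, extra)), detect_suspicion(o))
  # the all = TRUE option returns every qualifying anchor (both pairs here)
  anchors <- detect_suspicion(rbind(o, extra), all = TRUE)
  expect_equal(anchors, ts(c("2017-03-01 10:00", "2017-03-05 10:00")))
})

test_that("infection window spans -48 h to +24 h, truncated at encounter bounds", {
  w <- infection_window(ts("2017-03-03 12:00"))
  expect_equal(as.numeric(w$window_end) - as.numeric(w$window_start), 72 * 3600)
  expect_true(w$window_start < w$t_suspicion & w$t_suspicion < w$window_end)
  wt <- infection_window(ts("2017-03-03 12:00"),
                         enc_start = ts("2017-03-03 00:00"),
                         enc_end = ts("2017-03-03 20:00"))
  expect_equal(wt$window_start, ts("2017-03-03 00:00"))
  expect_equal(wt$window_end, ts("2017-03-03 20:00"))
})

test_that("Sepsis-1/2 requires SIRS inside the infection window", {
  start <- ts("2017-03-01 00:00"); end <- ts("2017-03-07 00:00")
  t_susp <- ts("2017-03-04 00:00")
  ep <- infection_window(t_susp, start, end)
  # febrile/tachycardic for one hour, then back to normal (carry-forward means
  # the crossing persists until the recovery entries)
  sirs_obs <- function(at) rbind(
    obs_df(at, "temperature", 39), obs_df(at, "heart_rate", 120),
    obs_df(at + hrs(1), "temperature", 37), obs_df(at + hrs(1), "heart_rate", 80))
  inside <- sirs_obs(t_susp - hrs(10))
  s1 <- criteria_series(inside, ep$window_start, ep$window_end, enc_start = start)
  expect_true(sepsis12_at_onset(ep, s1))
  # SIRS only 50 h before suspicion: outside the -48 h bound
  outside <- sirs_obs(t_susp - hrs(50))
  s2 <- criteria_series(outside, ep$window_start, ep$window_end, enc_start = start)
  expect_false(sepsis12_at_onset(ep, s2))
  s3 <- criteria_series(inside[0, ], ep$window_start, ep$window_end, enc_start = start)
  expect_false(sepsis12_at_onset(ep, s3))
})

test_that("Sepsis-3 absolute and delta modes differ on a flat SOFA trace", {
  start <- ts("2017-03-01 00:00"); end <- ts("2017-03-07 00:00")
  t_susp <- ts("2017-03-04 00:00")
  ep <- infection_window(t_susp, start, end)
  # constant SOFA 2 long before and through the window (platelets 90)
  flat <- obs_df(start, "platelets", 90)
  sf <- criteria_series(flat, ep$window_start, ep$window_end, enc_start = start)
  expect_true(sepsis3_at_onset(ep, sf, "absolute"))
  expect_false(sepsis3_at_onset(ep, sf, "delta"))
  # SOFA 0 at window start rising to 2 inside: both modes met
  rise <- obs_df(t_susp, "platelets", 90)
  sr <- criteria_series(rise, ep$window_start, ep$window_end, enc_start = start)
  expect_true(sepsis3_at_onset(ep, sr, "absolute"))
  expect_true(sepsis3_at_onset(ep, sr, "delta"))
})

test_that("a delta-mode positive implies an absolute-mode positive", {
  co <- generate_cohort(small_config(n = 40, seed = 31))
  ep <- adjudicate_cohort(co)
  expect_true(all(!ep$sepsis3_delta_met | ep$sepsis3_met))
})

test_that("adjudication reproduces the generator's planted truth", {
  co <- generate_cohort(small_config(n = 60, seed = 32))
  ep <- adjudicate_cohort(co)
  m <- merge(ep, co$truth, by = "encounter_id")
  # suspicion found exactly where an order pair was planted
  expect_identical(m$suspicion_found, m$detected)
  # planted episodes satisfy both consensus definitions at onset
  expect_true(all(m$sepsis12_met[m$detected]))
  expect_true(all(m$sepsis3_met[m$detected]))
  expect_equal(as.numeric(m$t_suspicion.x[m$detected]),
               as.numeric(m$t_suspicion.y[m$detected]))
  # no orders anywhere -> no episodes at all
  co2 <- co
  co2$orders <- co2$orders[0, ]
  ep2 <- adjudicate_cohort(co2)
  expect_false(any(ep2$suspicion_found))
})

test_that("a suspicion with flat-normal observations yields an all-false episode", {
  start <- ts("2017-03-01 00:00"); end <- ts("2017-03-06 00:00")
  enc <- data.frame(encounter_id = "E1", start = start, end = end)
  obs <- obs_df(start + hrs(0:20 * 4), "heart_rate", rep(75, 21))
  ord <- orders_df(c("2017-03-03 10:00", "2017-03-03 12:00"),
                   c("antibiotic_administration", "body_fluid_culture"))
  ep <- adjudicate_encounter(enc, obs, ord)
  expect_false(ep$sepsis12_met)
  expect_false(ep$sepsis3_met)
  expect_false(ep$sepsis3_delta_met)
  expect_equal(ep$onset_time, ts("2017-03-03 10:00"))
})
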