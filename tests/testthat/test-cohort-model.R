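test_that("encounter bounds take the earliest start and latest end candidate", {
  b <- derive_encounter_bounds(ts("2017-01-01 10:00"), ts("2017-01-01 18:00"),
                               ts("2017-01-01 09:30"), ts("2017-01-01 18:20"))
  expect_equal(b$start, ts("2017-01-01 09:30"))
  expect_equal(b$end, ts("2017-01-01 18:20"))

  # no vitals: administrative times stand alone
  b2 <- derive_encounter_bounds(ts("2017-01-01 10:00"), ts("2017-01-01 18:00"))
  expect_equal(b2$start, ts("2017-01-01 10:00"))
  expect_equal(b2$end, ts("2017-01-01 18:00"))

  # vitals strictly inside: administrative times dominate
  b3 <- derive_encounter_bounds(ts("2017-01-01 10:00"), ts("2017-01-01 18:00"),
                                ts("2017-01-01 10:05"), ts("2017-01-01 17:00"))
  expect_equal(b3$start, ts("2017-01-01 10:00"))
  expect_equal(b3$end, ts("2017-01-01 18:00"))
})

test_that("encounter bounds reject impossible inputs", {
  expect_error(derive_encounter_bounds(NA, NA, NA, ts("2017-01-01 12:00")),
               "no start or no end")
  expect_error(derive_encounter_bounds(ts("2017-01-02 10:00"), ts("2017-01-01 10:00")),
               "admission after discharge")
})

test_that("bound derivation is idempotent and symmetric in its candidates", {
  set.seed(11)
  for (i in 1:25) {
    adm <- ts("2017-02-01 00:00") + runif(1, 0, 86400)
    dis <- adm + runif(1, 3600, 10 * 86400)
    fv <- if (runif(1) < 0.8) adm + runif(1, -7200, 7200) else NA
    lv <- if (runif(1) < 0.8) dis + runif(1, -7200, 7200) else NA
    b <- derive_encounter_bounds(adm, dis, fv, lv)
    expect_lte(as.numeric(b$start), as.numeric(b$end))
    # idempotent: feeding derived bounds back as candidates changes nothing
    b2 <- derive_encounter_bounds(b$start, b$end, b$start, b$end)
    expect_equal(b2, b)
    # symmetric: swapping which candidate carries the extreme value
    b3 <- derive_encounter_bounds(
      if (is.na(fv)) adm else fv, if (is.na(lv)) dis else lv,
      adm, dis)
    expect_equal(b3, b)
  }
})

test_that("rating schedule enumerates the contained 2 PM instants", {
  expect_equal(rating_schedule(ts("2017-01-01 09:00"), ts("2017-01-03 16:00")),
               ts(c("2017-01-01 14:00", "2017-01-02 14:00", "2017-01-03 14:00")))
  expect_length(rating_schedule(ts("2017-01-01 15:00"), ts("2017-01-01 20:00")), 0)
  # inclusive at both bounds
  expect_equal(rating_schedule(ts("2017-01-01 13:59"), ts("2017-01-01 14:00")),
               ts("2017-01-01 14:00"))
  expect_equal(rating_schedule(ts("2017-01-01 14:00"), ts("2017-01-01 14:30")),
               ts("2017-01-01 14:00"))
})

test_that("schedule length is consistent with the day span", {
  set.seed(3)
  for (i in 1:50) {
    s <- ts("2017-01-01 00:00") + runif(1, 0, 86400)
    e <- s + runif(1, 0, 20 * 86400)
    len <- length(rating_schedule(s, e))
    span_days <- as.numeric(e - s, units = "days")
    expect_lte(abs(len - span_days), 1)
  }
})

test_that("editing rate counts schedule instants with an edited record", {
  sched <- ts("2017-01-01 14:00") + 86400 * (0:11)
  rec <- data.frame(rating_time = sched[1:11], edited = TRUE)
  expect_equal(editing_rate(rec, sched), 11 / 12)
  expect_equal(editing_rate(data.frame(rating_time = sched, edited = TRUE), sched), 1)
  # record present without any content-item reply is not edited
  rec2 <- data.frame(rating_time = sched[1], edited = FALSE)
  expect_equal(editing_rate(rec2, sched), 0)
  # duplicated records at an instant do not inflate the rate
  rec3 <- data.frame(rating_time = rep(sched[1:11], each = 3), edited = TRUE)
  expect_equal(editing_rate(rec3, sched), 11 / 12)
  expect_error(editing_rate(rec, sched[0]), "empty")
})

test_that("cohort validation drops pre-window observations and round-trips CSV", {
  enc <- data.frame(encounter_id = "E1",
                    pdms_admission = ts("2017-01-05 10:00"),
                    his_discharge = ts("2017-01-08 10:00"),
                    first_vital = ts("2017-01-05 09:50"),
                    last_vital = ts("2017-01-08 10:05"),
                    referral_group = "neurosurgical", icu_death = FALSE)
  obs <- obs_df(c("2017-01-01 00:00", "2017-01-04 00:00", "2017-01-06 00:00"),
                "heart_rate", c(70, 75, 80))
  ord <- orders_df("2017-01-06 08:00", "antibiotic_administration")
  gt <- data.frame(encounter_id = "E1", rating_time = ts("2017-01-05 14:00"),
                   working_diagnosis = "SIRS", suspicion_of_infection = "no",
                   edited = TRUE)
  expect_warning(co <- as_cohort(enc, obs, ord, gt), "dropped")
  expect_equal(nrow(co$observations), 2) # the one 4+ days early is gone
  expect_equal(co$encounters$start, ts("2017-01-05 09:50"))

  d <- withr::local_tempdir()
  write_cohort(co, d)
  expect_true(all(file.exists(file.path(d, c("encounters.csv", "observations.csv",
                                             "orders.csv", "gtsq.csv")))))
  co2 <- read_cohort(d)
  expect_equal(co2$encounters$start, co$encounters$start)
  expect_equal(co2$observations$value, co$observations$value)
  expect_equal(co2$gtsq$working_diagnosis, co$gtsq$working_diagnosis)
})

test_that("unknown labels and variables are rejected", {
  expect_error(wd_code("shocked"), "unknown working diagnosis")
  enc <- data.frame(encounter_id = "E1", pdms_admission = ts("2017-01-05 10:00"),
                    his_discharge = ts("2017-01-06 10:00"))
  bad_obs <- obs_df("2017-01-05 12:00", "lactate", 3)
  expect_error(as_cohort(enc, bad_obs, orders_df(character(0), character(0)),
                         data.frame(encounter_id = character(0),
                                    rating_time = ts(character(0)),
                                    working_diagnosis = character(0),
                                    edited = logical(0))),
               "unknown observation variable")
})
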