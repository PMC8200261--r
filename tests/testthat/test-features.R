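test_that("common-hour learning recovers point masses, uniformity and a
           planted schedule", {
  # all events in hour 8
  ev8 <- toy_events("T001", 8.5 + runif(150) * 0.4, "note_written")
  p <- learn_common_hours(ev8, features = "note_written")
  expect_identical(p[["note_written"]], 8L)

  # exactly uniform: every hour at the 1/24 threshold is common
  evu <- toy_events("T001", rep(0:23, 10) + 0.5, "note_written")
  p <- learn_common_hours(evu, features = "note_written")
  expect_identical(p[["note_written"]], 0:23)

  # 90% of mass on the routine schedule, 10% spread uniformly
  sched <- c(0, 4, 8, 12, 16, 20)
  hrs <- c(rep(sched, each = 90) + 0.2, rep(0:23, 25) + 0.7)
  evs <- toy_events("T001", hrs, "prn_administered")
  p <- learn_common_hours(evs, features = "prn_administered")
  expect_identical(p[["prn_administered"]], as.integer(sched))
})

test_that("rare features fall back to the configured schedule with a
           warning", {
  ev <- toy_events("T001", c(1.5, 2.5), "scheduled_withheld")
  expect_warning(
    p <- learn_common_hours(ev, features = "scheduled_withheld",
                            fallback_hours = c(0, 6, 12, 18)),
    "scheduled_withheld")
  expect_identical(p[["scheduled_withheld"]], c(0L, 6L, 12L, 18L))
  expect_identical(unname(attr(p, "source")["scheduled_withheld"]),
                   "configured")
})

test_that("the feature matrix has exactly 30 + 21 + 4 feature columns", {
  ft <- signal_bits()$features
  expect_identical(length(feature_columns("measurement")), 30L)
  expect_identical(length(feature_columns("note")), 21L)
  expect_identical(length(feature_columns("temporal")), 4L)
  expect_true(all(all_feature_columns() %in% names(ft)))
  expect_identical(ncol(ft), 56L)  # encounter_id + 55 features
  # one row per inpatient hour
  kept <- signal_bits()$kept
  stays <- ceiling(as.numeric(difftime(kept$discharge_time, kept$admit_time,
                                       units = "hours")))
  expect_identical(nrow(ft), as.integer(sum(stays)))
})

test_that("common and uncommon counts partition the window total", {
  ft <- signal_bits()$features
  # recompute unpartitioned totals with profiles that call every hour common
  sb <- signal_bits()
  all_common <- fixed_profiles(0:23)
  ft_all <- build_hourly_features(sb$events, sb$kept, all_common)
  for (f in measurement_features()) {
    lhs <- ft[[paste0(f, "_common")]] + ft[[paste0(f, "_uncommon")]]
    expect_identical(lhs, ft_all[[paste0(f, "_common")]])
    expect_true(all(ft_all[[paste0(f, "_uncommon")]] == 0))
  }
})

test_that("every cell matches the naive full-rescan oracle on randomized
           streams", {
  prof <- fixed_profiles()
  admit <- as.POSIXct("2017-03-06 05:00:00", tz = "UTC")
  set.seed(314)
  for (rep in 1:20) {
    n_hours <- sample(18:30, 1)
    n_ev <- sample(15:40, 1)
    hours <- runif(n_ev) * n_hours
    type <- sample(event_types(), n_ev, replace = TRUE)
    kind <- ifelse(type %in% c("vital_measurement", "vital_comment"),
                   sample(vital_kinds(), n_ev, replace = TRUE), NA)
    tags <- ifelse(type == "note_written",
                   vapply(seq_len(n_ev), function(i)
                     paste(sample(note_concepts(), sample(0:3, 1)),
                           collapse = ";"), character(1)),
                   NA)
    tags[tags == ""] <- NA
    ev <- toy_events("T001", hours, type, vital_kind = kind,
                     note_concepts = tags, admit = admit)
    ev$value[ev$event_type == "vital_measurement"] <- 80
    enc <- toy_encounters(n_hours, admit = admit)[1, ]

    got <- build_hourly_features(ev, enc, prof)
    want <- oracle_features(ev, admit, n_hours, prof)
    for (cn in colnames(want)) {
      expect_identical(as.integer(got[[cn]]), as.integer(want[, cn]),
                       label = sprintf("column %s (rep %d)", cn, rep))
    }
  }
})

test_that("adding an event never decreases any count covering its bin", {
  prof <- fixed_profiles()
  admit <- as.POSIXct("2017-03-06 05:00:00", tz = "UTC")
  set.seed(99)
  hours <- runif(25) * 24
  ev <- toy_events("T001", hours, "prn_administered", admit = admit)
  enc <- toy_encounters(24, admit = admit)[1, ]
  base <- build_hourly_features(ev, enc, prof)
  ev2 <- rbind(ev, toy_events("T001", 7.25, "note_written",
                              note_concepts = "pain_level", admit = admit))
  more <- build_hourly_features(ev2, enc, prof)
  num <- setdiff(all_feature_columns(), feature_columns("temporal"))
  diffs <- as.matrix(more[, num]) - as.matrix(base[, num])
  expect_true(all(diffs >= 0))
})

test_that("temporal columns follow the documented integer conventions", {
  admit <- as.POSIXct("2017-03-06 22:00:00", tz = "UTC")  # a Monday
  enc <- toy_encounters(30, admit = admit)[1, ]
  ev <- toy_events("T001", 1.5, "note_written", note_concepts = "monitoring",
                   admit = admit)
  ft <- build_hourly_features(ev, enc, fixed_profiles())
  expect_identical(ft$patient_hour, 0:29)
  expect_identical(ft$hour[1], 22L)
  expect_identical(ft$hour[3], 0L)           # rolls over midnight
  expect_identical(ft$day_of_week[1], 0L)    # Monday = 0
  expect_identical(ft$day_of_week[3], 1L)
  expect_identical(ft$month[1], 3L)
})

test_that("note-concept counting handles empty windows, multi-tag notes and
           bad labels", {
  admit <- as.POSIXct("2017-03-06 00:00:00", tz = "UTC")
  enc <- toy_encounters(30, admit = admit)[1, ]
  ev <- toy_events("T001", 5.5, "note_written",
                   note_concepts = "pain_level;monitoring", admit = admit)
  nc <- count_note_concepts(ev, enc)
  expect_identical(ncol(nc), 23L)  # keys + 21 concepts
  expect_true(all(nc[nc$patient_hour < 5, feature_columns("note")] == 0))
  expect_identical(nc$note_pain_level[nc$patient_hour == 5], 1L)
  expect_identical(nc$note_monitoring[nc$patient_hour == 5], 1L)
  expect_identical(sum(as.matrix(nc[nc$patient_hour == 5,
                                    feature_columns("note")])), 2L)
  # trailing 12-hour window: present through hour 16, gone at 17
  expect_identical(nc$note_pain_level[nc$patient_hour == 16], 1L)
  expect_identical(nc$note_pain_level[nc$patient_hour == 17], 0L)

  bad <- toy_events("T001", 2.5, "note_written",
                    note_concepts = "not_a_concept", admit = admit)
  expect_error(count_note_concepts(bad, enc), "not_a_concept")
})

test_that("events referencing unknown encounters raise a referential error", {
  enc <- toy_encounters(30)[1, ]
  ev <- toy_events("GHOST", 2.5, "note_written")
  expect_error(build_hourly_features(ev, enc, fixed_profiles()), "GHOST")
})
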