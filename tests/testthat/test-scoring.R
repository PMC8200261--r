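test_that("all-normal vitals score zero on both comparators", {
  expect_identical(mews_total(hr = 75, rr = 13, sbp = 120, temp = 36.8), 0L)
  expect_identical(news_total(rr = 14, spo2 = 98, supp_o2 = FALSE,
                              temp = 36.8, sbp = 120, hr = 75), 0L)
})

test_that("engineered component sums land in the printed high bands", {
  # MEWS components 3 + 2 + 0 + 0 + 0 = 5 -> high
  s <- mews_total(hr = 132, rr = 12, sbp = 78, temp = 37, avpu = "A")
  expect_identical(s, 5L)
  expect_identical(as.character(categorize(s, score_bands("MEWS"))), "high")
  # NEWS 2 + 2 + 2 + 0 + 0 + 1 + 0 = 7 -> high
  s <- news_total(rr = 22, spo2 = 93, supp_o2 = TRUE, temp = 36.5,
                  sbp = 115, hr = 95, avpu = "A")
  expect_identical(s, 7L)
  expect_identical(as.character(categorize(s, score_bands("NEWS"))), "high")
})

test_that("randomized vitals match the independent lookup oracle", {
  set.seed(1234)
  n <- 500
  hr <- runif(n, 25, 180); rr <- runif(n, 4, 45)
  sbp <- runif(n, 55, 240); temp <- runif(n, 33.5, 41)
  spo2 <- round(runif(n, 80, 100)); supp <- runif(n) < 0.3
  avpu <- sample(c("A", "V", "P", "U"), n, replace = TRUE)
  expect_equal(as.numeric(mews_total(hr, rr, sbp, temp, avpu)),
               as.numeric(oracle_mews(hr, rr, sbp, temp, avpu)))
  expect_equal(as.numeric(news_total(rr, spo2, supp, temp, sbp, hr, avpu)),
               as.numeric(oracle_news(rr, spo2, supp, temp, sbp, hr, avpu)))
})

test_that("missing components make the score undefined", {
  expect_true(is.na(mews_total(hr = NA, rr = 13, sbp = 120, temp = 37)))
  expect_true(is.na(news_total(rr = 14, spo2 = NA, supp_o2 = FALSE,
                               temp = 37, sbp = 120, hr = 70)))
})

test_that("category mapping is exact over the full integer score ranges", {
  mews_cat <- as.character(categorize(0:14, score_bands("MEWS")))
  expect_identical(mews_cat, c(rep("low", 3), rep("moderate", 2),
                               rep("high", 10)))
  news_cat <- as.character(categorize(0:20, score_bands("NEWS")))
  expect_identical(news_cat, c(rep("low", 4), rep("moderate", 3),
                               rep("high", 14)))
  expect_error(categorize(-1, score_bands("MEWS")), "nonnegative")
  expect_error(score_bands("CONCERN"), "cutpoints")
  expect_error(score_bands("MEWS", cutpoints = c(5, 3)), "increasing")
})

test_that("quantile cutpoints put about 15% of training hours in yellow and
           5% in red", {
  sb <- signal_bits()
  scorer <- fit_reference_scorer(sb$features, sb$first_events,
                                 train_frac = 0.6, seed = 3,
                                 min_train_events = 10)
  series <- concern_score_series(
    scorer, sb$features[sb$features$encounter_id %in%
                          scorer$train_encounters, ])
  share <- prop.table(table(series$category))
  expect_equal(unname(share[["moderate"]]), 0.15, tolerance = 0.25)
  expect_equal(unname(share[["high"]]), 0.05, tolerance = 0.25)
})

test_that("scorer coefficients are invariant to row order", {
  sb <- signal_bits()
  ids <- unique(sb$features$encounter_id)
  tr <- ids[seq_len(60)]
  a <- fit_reference_scorer(sb$features, sb$first_events,
                            train_encounters = tr, min_train_events = 5)
  set.seed(8)
  shuffled <- sb$features[sample(nrow(sb$features)), ]
  b <- fit_reference_scorer(shuffled, sb$first_events,
                            train_encounters = tr, min_train_events = 5)
  expect_equal(a$coefficients, b$coefficients, tolerance = 1e-6)
  expect_equal(a$cutpoints, b$cutpoints, tolerance = 1e-8)
})

test_that("a feature-independent outcome yields chance-level discrimination", {
  aucs <- vapply(1:5, function(s) {
    cfg <- sim_config(n_encounters = 150,
                      concern_multipliers = default_concern_multipliers() * 0,
                      drift_max = 0, seed = 600 + s)
    co <- simulate_cohort(cfg)
    kept <- apply_inclusion_filters(co$encounters)
    ev <- co$events[co$events$encounter_id %in% kept$encounter_id, ]
    oc <- co$outcomes[co$outcomes$encounter_id %in% kept$encounter_id, ]
    ft <- build_hourly_features(ev, kept,
                                suppressWarnings(learn_common_hours(ev)))
    fe <- composite_first_event(oc, kept)
    scorer <- fit_reference_scorer(ft, fe, seed = s, min_train_events = 5)
    test_ft <- ft[ft$encounter_id %in% scorer$test_encounters, ]
    lab <- concernews:::label_rows(test_ft, fe, scorer$horizon_hours)
    auc_of(predict(scorer, lab), lab$label)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("under a strong behavioral signal, pre-event hours outscore
           non-event hours", {
  sb <- signal_bits()
  cs <- crossfit_concern_scores(sb$features, sb$first_events, seed = 4,
                                min_train_events = 10)
  m <- merge(cs, sb$first_events, by = "encounter_id")
  m <- m[m$patient_hour < m$end_time, ]
  pre <- m$has_event & (m$event_time - m$patient_hour) <= 48 &
    (m$event_time - m$patient_hour) > 6
  expect_gt(mean(m$score[pre]), mean(m$score[!m$has_event]))
})

test_that("perfectly separated training data raises a fit error advising
           ridge", {
  ids <- sprintf("S%02d", 1:30)
  rows <- do.call(rbind, lapply(ids, function(id) {
    ft <- data.frame(encounter_id = id, matrix(0, 4, 55))
    names(ft)[-1] <- all_feature_columns()
    ft$patient_hour <- 0:3
    ft
  }))
  has_ev <- as.integer(substring(ids, 2)) <= 15
  rows$note_pain_level <- as.integer(rows$encounter_id %in% ids[has_ev])
  set.seed(77)
  rows$RR_comment_common <- runif(nrow(rows))  # noise, keeps scores distinct
  fe <- data.frame(encounter_id = ids,
                   event_time = ifelse(has_ev, 5.5, NA),
                   censor_time = 10, end_time = ifelse(has_ev, 5.5, 10),
                   has_event = has_ev)
  expect_error(
    fit_reference_scorer(rows, fe, train_encounters = ids,
                         regularize = "none", min_train_events = 2),
    "separation|converge")
  scorer <- fit_reference_scorer(rows, fe, train_encounters = ids,
                                 regularize = "ridge", min_train_events = 2)
  expect_true(all(is.finite(scorer$coefficients)))
})

test_that("constant features give a constant category", {
  sb <- signal_bits()
  scorer <- fit_reference_scorer(sb$features, sb$first_events, seed = 3,
                                 min_train_events = 10)
  const <- sb$features[rep(1, 6), ]
  const$patient_hour <- 0:5
  series <- concern_score_series(scorer, const)
  expect_identical(length(unique(series$category)), 1L)
  expect_identical(series$patient_hour, 1:6)  # stamped one hour after data
})

test_that("comparator series change only at hours with new observations", {
  admit <- as.POSIXct("2017-03-06 00:00:00", tz = "UTC")
  enc <- toy_encounters(20, admit = admit)[1, ]
  mk <- function(h, kind, val) {
    e <- toy_events("T001", h, "vital_measurement", vital_kind = kind,
                    value = val, admit = admit)
    e$avpu <- "A"
    if (kind == "SpO2") e$oxygen_supplemental <- FALSE
    e
  }
  ev <- rbind(mk(2.5, "HR", 75), mk(2.5, "RR", 13), mk(2.5, "BP", 120),
              mk(2.5, "Temp", 36.8), mk(2.5, "SpO2", 98),
              mk(10.2, "HR", 120))
  s <- comparator_score_series(ev, enc, "MEWS")
  expect_true(all(is.na(s$score[s$patient_hour <= 2])))   # before any vitals
  expect_equal(s$score[s$patient_hour == 3], 0)
  expect_equal(s$score[s$patient_hour == 10], 0)      # 10.2 not yet seen
  expect_equal(s$score[s$patient_hour == 11], 2)      # HR 120 -> 2 points
  expect_equal(unique(s$score[s$patient_hour %in% 3:10]), 0)
  # staleness: the 2.5 h vitals expire 12 h later; only HR remains after
  expect_true(all(is.na(s$score[s$patient_hour >= 15])))
  changes <- which(diff(s$score[!is.na(s$score)]) != 0)
  expect_identical(length(changes), 1L)
})
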