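test_that("the composite endpoint takes the first component occurrence", {
  enc <- toy_encounters(c(100, 100, 100))
  oc <- data.frame(encounter_id = c("T001", "T001", "T002"),
                   event_time = c(41, 30, 55),
                   component = c("mortality", "rapid_response", "sepsis"))
  fe <- composite_first_event(oc, enc)
  expect_identical(fe$event_time[fe$encounter_id == "T001"], 30)
  expect_true(fe$has_event[fe$encounter_id == "T002"])
  expect_false(fe$has_event[fe$encounter_id == "T003"])
  expect_identical(fe$end_time[fe$encounter_id == "T003"], 100)

  # randomized component sets against a plain loop-min oracle
  set.seed(42)
  for (rep in 1:10) {
    n_oc <- sample(1:6, 1)
    oc <- data.frame(encounter_id = sample(c("T001", "T002"), n_oc,
                                           replace = TRUE),
                     event_time = round(runif(n_oc, 1, 99), 1),
                     component = sample(outcome_components(), n_oc,
                                        replace = TRUE))
    fe <- composite_first_event(oc, enc)
    for (id in unique(oc$encounter_id)) {
      want <- Inf
      for (i in seq_len(nrow(oc))) {
        if (oc$encounter_id[i] == id) want <- min(want, oc$event_time[i])
      }
      expect_identical(fe$event_time[fe$encounter_id == id], want)
    }
  }

  bad <- data.frame(encounter_id = "T001", event_time = 101,
                    component = "sepsis")
  expect_error(composite_first_event(bad, enc), "after discharge")
})

toy_scores <- function(id, cats, system = "S") {
  data.frame(encounter_id = id, patient_hour = seq_along(cats),
             system = system, score = 0, category = cats,
             stringsAsFactors = FALSE)
}

toy_fe <- function(ids, event_time, censor_time) {
  data.frame(encounter_id = ids, event_time = event_time,
             censor_time = censor_time,
             end_time = pmin(event_time, censor_time, na.rm = TRUE),
             has_event = !is.na(event_time), stringsAsFactors = FALSE)
}

test_that("counting-process construction run-length encodes categories", {
  # constant low, censored: one interval
  sc <- toy_scores("A", rep("low", 20))
  fe <- toy_fe("A", NA, 20.5)
  rec <- to_counting_process(sc, fe)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$event, 0L)
  expect_equal(rec$stop - rec$start, 19.5)  # hours 1..20 then censor

  # category change at hour 10 splits the exposure
  sc <- toy_scores("A", c(rep("low", 9), rep("moderate", 11)))
  fe <- toy_fe("A", 18.25, 30)
  rec <- to_counting_process(sc, fe)
  expect_identical(nrow(rec), 2L)
  expect_equal(rec$start, c(1, 10))
  expect_equal(rec$stop, c(10, 18.25))
  expect_identical(rec$event, c(0L, 1L))
  expect_identical(rec$s_moderate, c(0L, 1L))
})

test_that("total exposure is conserved under arbitrary category churn", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    cats <- sample(c("low", "moderate", "high"), n, replace = TRUE)
    ev <- if (runif(1) < 0.5) round(runif(1, 2, n), 2) else NA
    fe <- toy_fe("A", ev, n + runif(1))
    sc <- toy_scores("A", cats)
    rec <- to_counting_process(sc, fe)
    expect_equal(sum(rec$stop - rec$start), fe$end_time - 1,
                 tolerance = 1e-9)
    expect_identical(sum(rec$event), as.integer(!is.na(ev)))
  }
})

test_that("the partial-likelihood fit matches a closed-form toy solution", {
  # three subjects, one binary covariate; events at t=1 (x=0, risk set of
  # three) and t=2 (x=1, risk set {A, C}); the score equation
  # u/(u+2) + u/(u+1) = 1 with u = exp(beta) has the root u = sqrt(2)
  rec <- data.frame(
    encounter_id = c("A", "B", "C"),
    start = c(0, 0, 0), stop = c(2, 1, 3), event = c(1L, 1L, 0L),
    x_high = c(1L, 0L, 0L))
  fit <- fit_time_varying_cox(rec, covariates = "x_high", min_events = 2)
  expect_equal(unname(attr(fit, "coef")), log(2) / 2, tolerance = 1e-6)
  expect_equal(fit$hr, sqrt(2), tolerance = 1e-6)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)
})

test_that("permuted category series give null-calibrated hazard ratios", {
  # permuting whole series across encounters severs any link between the
  # covariate path and the event times while preserving serial structure
  sim <- simulate_planted_hazard(150, hazard_ratio = 4, seed = 20)
  sc <- data.table::as.data.table(sim$scores)
  series <- split(sc$category, sc$encounter_id)
  lens <- vapply(series, length, integer(1))
  ids <- names(series)
  inside <- 0
  logs <- numeric(40)
  set.seed(21)
  for (i in 1:40) {
    donor <- sample(seq_along(ids))
    perm <- data.table::copy(sc)
    perm[, category := unlist(lapply(seq_along(ids), function(k)
      rep_len(series[[donor[k]]], lens[k])))]
    rec <- to_counting_process(perm, sim$first_events)
    fit <- suppressWarnings(
      fit_time_varying_cox(rec, covariates = "planted_high"))
    b <- unname(attr(fit, "coef")); se <- unname(attr(fit, "se"))
    logs[i] <- b
    if (abs(b) < 2 * se) inside <- inside + 1
  }
  expect_gte(inside, 35)
  expect_lt(abs(mean(logs)), 0.15)
})

test_that("a planted hazard multiplier is recovered by the Cox fit", {
  sim <- simulate_planted_hazard(800, hazard_ratio = 5, seed = 12)
  rec <- to_counting_process(sim$scores, sim$first_events)
  fit <- suppressWarnings(
    fit_time_varying_cox(rec, covariates = "planted_high"))
  expect_lt(abs(fit$hr / 5 - 1), 0.25)
})

test_that("constant covariates are dropped with a warning and few events
           refuse to fit", {
  sc <- toy_scores("A", rep("low", 20))
  fe <- toy_fe("A", 10.5, 20)
  rec <- to_counting_process(sc, fe)
  expect_error(fit_time_varying_cox(rec), "events")
  sim <- simulate_planted_hazard(200, hazard_ratio = 3, seed = 5)
  rec <- to_counting_process(sim$scores, sim$first_events)
  expect_warning(fit_time_varying_cox(rec), "planted_moderate")
})
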