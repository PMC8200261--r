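# Shared fixtures, built in code and cached for the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# a small default-signal cohort carried through the whole pipeline
signal_bits <- function() {
  cached("signal", {
    cfg <- sim_config(n_encounters = 150, seed = 42)
    co <- simulate_cohort(cfg)
    kept <- apply_inclusion_filters(co$encounters)
    ev <- co$events[co$events$encounter_id %in% kept$encounter_id, ]
    oc <- co$outcomes[co$outcomes$encounter_id %in% kept$encounter_id, ]
    prof <- suppressWarnings(learn_common_hours(ev))
    ft <- build_hourly_features(ev, kept, prof)
    fe <- composite_first_event(oc, kept)
    list(cfg = cfg, cohort = co, kept = kept, events = ev, outcomes = oc,
         profiles = prof, features = ft, first_events = fe)
  })
}

# an isolated-rate configuration: no forced vitals, flat day/night weights,
# no events -- used for the Poisson count oracles
flat_rate_config <- function(n_encounters, rates, seed,
                             multipliers = default_concern_multipliers() * 0,
                             event_fraction = 0, los = 100) {
  base <- default_base_rates() * 0
  base[names(rates)] <- rates
  sim_config(
    n_encounters = n_encounters, event_fraction = event_fraction,
    base_rates = base, concern_multipliers = multipliers,
    vitals_schedule = integer(0), schedule_weight = rep(1, 24),
    los_distribution = list(meanlog = log(los), sdlog = 1e-9,
                            min = los, max = los),
    drift_max = 0, hospice_fraction = 0, seed = seed)
}

# hand-built encounter table: admits at a fixed instant, stays in hours
toy_encounters <- function(stay_hours, age = 50, hospice = FALSE,
                           admit = as.POSIXct("2017-03-06 00:00:00",
                                              tz = "UTC")) {
  n <- length(stay_hours)
  data.frame(
    encounter_id = sprintf("T%03d", seq_len(n)),
    patient_id = sprintf("TP%03d", seq_len(n)),
    age = rep_len(age, n),
    unit_type = "medsurg",
    admit_time = rep(admit, n),
    discharge_time = admit + stay_hours * 3600,
    hospice_flag = rep_len(hospice, n),
    stringsAsFactors = FALSE
  )
}

# hand-built event rows at given hours since admission
toy_events <- function(encounter_id, hours, event_type, vital_kind = NA,
                       value = NA, note_concepts = NA,
                       admit = as.POSIXct("2017-03-06 00:00:00", tz = "UTC")) {
  n <- length(hours)
  data.frame(
    encounter_id = rep_len(encounter_id, n),
    timestamp = admit + round(hours * 3600),
    event_type = rep_len(event_type, n),
    vital_kind = rep_len(vital_kind, n),
    value = rep_len(value, n),
    oxygen_supplemental = NA,
    avpu = NA_character_,
    note_concepts = rep_len(note_concepts, n),
    stringsAsFactors = FALSE
  )
}

# profiles with fixed common hours for every base feature
fixed_profiles <- function(common = c(0L, 4L, 8L, 12L, 16L, 20L)) {
  p <- stats::setNames(rep(list(sort(common)),
                           length(measurement_features())),
                       measurement_features())
  structure(p, source = stats::setNames(rep("configured", length(p)),
                                        names(p)),
            threshold = 1 / 24, class = "common_time_profiles")
}

# rank-based AUC
auc_of <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label); n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
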