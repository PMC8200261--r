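#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic cohort
#' generator. The generator emulates the statistical structure the analysis
#' assumes: documentation events arrive from inhomogeneous Poisson processes
#' whose rates are modulated by a latent clinician-concern ramp that starts
#' tens of hours before a composite deterioration event, while vital-sign
#' values drift toward abnormal ranges only in the final hours.
#'
#' Default rates are assumptions chosen for a desk-scale benchmark cohort,
#' not measured hospital quantities; see the package vignette for the
#' rationale behind each value.
#'
#' @param n_encounters number of encounters to simulate.
#' @param event_fraction expected fraction of encounters experiencing the
#'   composite outcome before discharge (deterioration-enriched by default
#'   so that a few hundred encounters already carry enough events for stable
#'   model fits). Events are assigned by a constant hazard calibrated to
#'   this fraction, so time-at-risk itself is uninformative.
#' @param behavioral_onset_hours hours before the event at which the concern
#'   ramp begins (default 48).
#' @param physiological_onset_hours hours before the event at which vital
#'   drift begins (default 6). Must not exceed \code{behavioral_onset_hours}.
#' @param base_rates named numeric vector of expected events/hour under the
#'   standard-of-care schedule, one entry per Poisson stream (five vital
#'   measurements, five vital comments, \code{prn_administered},
#'   \code{scheduled_withheld}, \code{note_written}).
#' @param concern_multipliers named numeric vector (same names): maximum
#'   excess-rate multiplier at full concern. A value m scales the stream rate
#'   by \code{1 + m * c(t)}.
#' @param vitals_schedule integer hours of day at which routine vitals are
#'   charted (default every 4 hours: 0, 4, 8, 12, 16, 20).
#' @param schedule_weight length-24 positive vector of hour-of-day
#'   documentation intensity multipliers (default: heavier day shift).
#' @param los_distribution list(meanlog, sdlog, min, max): log-normal
#'   length-of-stay in hours, clamped.
#' @param age_distribution list(mean, sd, min, max): normal age in years,
#'   clamped.
#' @param drift_max amplitude in [0, 1] scaling the physiological drift ramp;
#'   0 disables physiological deterioration entirely.
#' @param concern_shape "linear" (default) or "sigmoid" ramp shape.
#' @param hospice_fraction fraction of encounters flagged hospice.
#' @param unit_mix named probabilities over medsurg/stepdown/icu.
#' @param outcome_mix named probabilities over the composite components.
#' @param admit_window character(2) ISO dates bounding admission times.
#' @param seed integer seed; identical (config, seed) pairs produce
#'   byte-identical output tables.
#' @return object of class \code{sim_config}
#' @export
sim_config <- function(n_encounters = 500,
                       event_fraction = 0.3,
                       behavioral_onset_hours = 48,
                       physiological_onset_hours = 6,
                       base_rates = default_base_rates(),
                       concern_multipliers = default_concern_multipliers(),
                       vitals_schedule = c(0L, 4L, 8L, 12L, 16L, 20L),
                       schedule_weight = default_schedule_weight(),
                       los_distribution = list(meanlog = log(96), sdlog = 0.5,
                                               min = 8, max = 1440),
                       age_distribution = list(mean = 65, sd = 15,
                                               min = 16, max = 100),
                       drift_max = 1,
                       concern_shape = c("linear", "sigmoid"),
                       hospice_fraction = 0.02,
                       unit_mix = c(medsurg = 0.6, stepdown = 0.25, icu = 0.15),
                       outcome_mix = c(mortality = 0.15, cardiac_arrest = 0.1,
                                       icu_transfer = 0.3, rapid_response = 0.3,
                                       sepsis = 0.15),
                       admit_window = c("2015-01-01", "2018-12-31"),
                       seed = 1L) {
  concern_shape <- match.arg(concern_shape)

  if (!is.numeric(n_encounters) || n_encounters < 1) {
    stop_config("n_encounters", "must be a positive count")
  }
  if (!is.numeric(event_fraction) || event_fraction < 0 || event_fraction > 1) {
    stop_config("event_fraction", "must lie in [0, 1]")
  }
  if (behavioral_onset_hours <= 0) {
    stop_config("behavioral_onset_hours", "must be positive")
  }
  if (physiological_onset_hours <= 0) {
    stop_config("physiological_onset_hours", "must be positive")
  }
  if (behavioral_onset_hours < physiological_onset_hours) {
    stop_config("behavioral_onset_hours",
                "must be >= physiological_onset_hours")
  }

  streams <- poisson_streams()
  base_rates <- unlist(base_rates)
  concern_multipliers <- unlist(concern_multipliers)
  if (!setequal(names(base_rates), streams)) {
    stop_config("base_rates", paste("must be named with exactly:",
                                    paste(streams, collapse = ", ")))
  }
  if (any(!is.finite(base_rates)) || any(base_rates < 0)) {
    bad <- names(base_rates)[!is.finite(base_rates) | base_rates < 0]
    stop_config("base_rates", paste("negative or non-finite rate for",
                                    paste(bad, collapse = ", ")))
  }
  if (!setequal(names(concern_multipliers), streams)) {
    stop_config("concern_multipliers", paste("must be named with exactly:",
                                             paste(streams, collapse = ", ")))
  }
  if (any(!is.finite(concern_multipliers)) || any(concern_multipliers < 0)) {
    stop_config("concern_multipliers", "multipliers must be >= 0")
  }
  vitals_schedule <- as.integer(vitals_schedule)
  if (any(is.na(vitals_schedule)) || any(vitals_schedule < 0) ||
      any(vitals_schedule > 23)) {
    stop_config("vitals_schedule", "hours must be integers in 0..23")
  }
  if (length(schedule_weight) != 24 || any(schedule_weight <= 0)) {
    stop_config("schedule_weight", "must be 24 positive weights")
  }
  if (!is.numeric(drift_max) || drift_max < 0 || drift_max > 1) {
    stop_config("drift_max", "must lie in [0, 1]")
  }
  if (hospice_fraction < 0 || hospice_fraction > 1) {
    stop_config("hospice_fraction", "must lie in [0, 1]")
  }
  for (blk in c("los_distribution", "age_distribution")) {
    v <- get(blk)
    if (!is.list(v) || v$min > v$max) {
      stop_config(blk, "must be a list with min <= max")
    }
  }
  if (abs(sum(unit_mix) - 1) > 1e-8 || any(unit_mix < 0)) {
    stop_config("unit_mix", "must be nonnegative probabilities summing to 1")
  }
  if (abs(sum(outcome_mix) - 1) > 1e-8 ||
      !setequal(names(outcome_mix), outcome_components())) {
    stop_config("outcome_mix",
                "must be probabilities over the five composite components")
  }

  structure(list(
    n_encounters = as.integer(n_encounters),
    event_fraction = event_fraction,
    behavioral_onset_hours = behavioral_onset_hours,
    physiological_onset_hours = physiological_onset_hours,
    base_rates = base_rates[streams],
    concern_multipliers = concern_multipliers[streams],
    vitals_schedule = sort(unique(vitals_schedule)),
    schedule_weight = as.numeric(schedule_weight),
    los_distribution = los_distribution,
    age_distribution = age_distribution,
    drift_max = drift_max,
    concern_shape = concern_shape,
    hospice_fraction = hospice_fraction,
    unit_mix = unit_mix,
    outcome_mix = outcome_mix[outcome_components()],
    admit_window = admit_window,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default per-stream baseline documentation rates (events/hour)
#'
#' Discretionary (non-scheduled) charting on top of the forced routine-vitals
#' schedule. Assumed values for the benchmark cohort, not hospital estimates.
#' @return named numeric vector over the 13 Poisson streams
#' @export
default_base_rates <- function() {
  r <- c(rep(0.06, 5), rep(0.02, 5), 0.04, 0.01, 0.10)
  names(r) <- poisson_streams()
  r
}

#' Default concern multipliers (max excess-rate factor at full concern)
#' @return named numeric vector over the 13 Poisson streams
#' @export
default_concern_multipliers <- function() {
  m <- rep(3, 13)
  names(m) <- poisson_streams()
  m
}

#' Default hour-of-day documentation weights (heavier day shift)
#' @return numeric vector of length 24 (hour 0 first)
#' @export
default_schedule_weight <- function() {
  w <- rep(0.7, 24)
  w[8:21] <- 1.3  # hours 7..20
  w
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_encounters, "encounters,",
      sprintf("event fraction %.2f,", x$event_fraction),
      sprintf("concern onset %gh / drift onset %gh,", x$behavioral_onset_hours,
              x$physiological_onset_hours),
      "seed", x$seed, "\n")
  invisible(x)
}
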