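#' Latent concern and physiological-drift trajectories
#'
#' For an event encounter, clinician concern \code{c(t)} ramps from 0 to 1
#' over the \code{behavioral_onset_hours} preceding the event, and the
#' physiological drift \code{d(t)} ramps analogously over the (much shorter)
#' \code{physiological_onset_hours}, scaled by \code{drift_max}. Non-event
#' encounters carry identically zero trajectories. Hourly values are the ramp
#' evaluated at the hour midpoint.
#'
#' @param event_time hours since admission of the composite event, or NA
#' @param los length of stay in hours
#' @param config a [sim_config()]
#' @return list with per-hour \code{concern} and \code{drift} vectors
#'   (length \code{ceiling(los)}), plus \code{event_time} and \code{los}
#' @export
simulate_latent_trajectory <- function(event_time, los, config) {
  if (los <= 0) stop("los must be positive", call. = FALSE)
  n_hours <- ceiling(los)
  mids <- seq_len(n_hours) - 0.5
  if (is.null(event_time) || is.na(event_time)) {
    return(list(concern = numeric(n_hours), drift = numeric(n_hours),
                event_time = NA_real_, los = los))
  }
  if (event_time > los || event_time <= 0) {
    stop("event_time must lie in (0, los]", call. = FALSE)
  }
  list(
    concern = ramp_value(mids, event_time, config$behavioral_onset_hours,
                         config$concern_shape),
    drift = config$drift_max *
      ramp_value(mids, event_time, config$physiological_onset_hours,
                 config$concern_shape),
    event_time = event_time,
    los = los
  )
}

# monotone ramp from 0 at (event - onset) to 1 at event
ramp_value <- function(t, event_time, onset, shape = "linear") {
  u <- (t - (event_time - onset)) / onset
  if (shape == "sigmoid") {
    raw <- stats::plogis((u - 0.5) * 10)
    # rescale so the ramp is exactly 0 before onset and ~1 at the event
    out <- (raw - stats::plogis(-5)) / (stats::plogis(5) - stats::plogis(-5))
    out[u <= 0] <- 0
    pmin(pmax(out, 0), 1)
  } else {
    pmin(pmax(u, 0), 1)
  }
}

# vital-sign value model: normal-range center drifting toward an abnormal
# target as d(t) rises; draws are clipped to mean +/- 2 sd so that calm
# (d = 0) patients stay inside the zero-point bands of both comparator tables
vital_value_params <- function() {
  data.frame(
    vital_kind = vital_kinds(),
    center = c(75, 13, 120, 36.8, 98),
    target = c(135, 28, 82, 38.8, 89),
    sd     = c(6, 0.5, 4, 0.15, 0.8),
    lo     = c(20, 4, 40, 33, 50),
    hi     = c(220, 60, 260, 42, 100),
    digits = c(0, 0, 0, 1, 0)
  )
}

#' Simulate the clinical event stream of one encounter
#'
#' Events of each stream are drawn from an inhomogeneous Poisson process with
#' hourly rate \code{base_rate * schedule_weight(hour-of-day) *
#' (1 + multiplier * c(t))}. Routine vitals (all five kinds, one shared
#' timestamp) are additionally forced at every \code{vitals_schedule}
#' wall-clock hour fully contained in the at-risk period. Vital values are
#' drawn around a mean interpolating from a normal-range center toward a
#' MEWS/NEWS-abnormal target as the drift \code{d(t)} rises; blood pressure
#' carries the systolic value. SpO2 rows carry a supplemental-oxygen flag
#' (d > 0.5) and measurement rows an AVPU consciousness assessment ("V"
#' rather than "A" once d > 0.8). Note events carry concept tags from the
#' 21-label vocabulary, with tag counts increasing with concern.
#'
#' The stream stops at \code{min(los, event_time)}.
#'
#' @param trajectory result of [simulate_latent_trajectory()]
#' @param encounter one-row data.frame with \code{encounter_id} and
#'   \code{admit_time} (POSIXct, UTC)
#' @param config a [sim_config()]
#' @return data.frame of clinical events ordered by timestamp
#' @export
simulate_events <- function(trajectory, encounter, config) {
  end_time <- min(trajectory$los,
                  if (is.na(trajectory$event_time)) Inf else trajectory$event_time)
  n_hours <- ceiling(end_time)
  t0 <- seq_len(n_hours) - 1                 # hour starts
  exposure <- pmin(end_time, t0 + 1) - t0    # fraction of hour at risk
  admit <- encounter$admit_time
  admit_hod <- hour_of_day(admit)
  hod <- (admit_hod + t0) %% 24
  sw <- config$schedule_weight[hod + 1]
  concern <- trajectory$concern[seq_len(n_hours)]
  drift <- trajectory$drift[seq_len(n_hours)]

  rows <- vector("list", length(poisson_streams()) + 1L)
  names(rows) <- c(poisson_streams(), ".forced")

  for (stream in poisson_streams()) {
    lambda <- config$base_rates[[stream]] * sw *
      (1 + config$concern_multipliers[[stream]] * concern) * exposure
    n <- stats::rpois(n_hours, lambda)
    if (sum(n) == 0L) next
    idx <- rep.int(seq_len(n_hours), n)
    times <- t0[idx] + stats::runif(sum(n)) * exposure[idx]
    rows[[stream]] <- data.frame(time = times, stream = stream,
                                 hour_idx = idx, stringsAsFactors = FALSE)
  }

  # forced routine vitals: all five kinds charted together within the first
  # 15 minutes of each fully-covered schedule hour
  sched_idx <- which(hod %in% config$vitals_schedule & exposure >= 1)
  if (length(sched_idx)) {
    offs <- stats::runif(length(sched_idx)) * 0.25
    times <- rep(t0[sched_idx] + offs, each = 5L)
    rows[[".forced"]] <- data.frame(
      time = times,
      stream = rep(paste0(vital_kinds(), "_measurement"), length(sched_idx)),
      hour_idx = rep(sched_idx, each = 5L),
      stringsAsFactors = FALSE
    )
  }

  ev <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(ev) || nrow(ev) == 0L) {
    return(empty_events())
  }
  ev <- ev[order(ev$time), , drop = FALSE]
  # whole-second timestamps (exact CSV round trips), never past the stream end
  secs <- pmin(round(ev$time * 3600), floor(end_time * 3600))

  out <- data.frame(
    encounter_id = encounter$encounter_id,
    timestamp = admit + secs,
    event_type = NA_character_,
    vital_kind = NA_character_,
    value = NA_real_,
    oxygen_supplemental = NA,
    avpu = NA_character_,
    note_concepts = NA_character_,
    stringsAsFactors = FALSE
  )

  is_meas <- grepl("_measurement$", ev$stream)
  is_comm <- grepl("_comment$", ev$stream)
  out$event_type[is_meas] <- "vital_measurement"
  out$event_type[is_comm] <- "vital_comment"
  out$event_type[ev$stream == "prn_administered"] <- "prn_administered"
  out$event_type[ev$stream == "scheduled_withheld"] <- "scheduled_withheld"
  out$event_type[ev$stream == "note_written"] <- "note_written"
  out$vital_kind[is_meas | is_comm] <- sub("_(measurement|comment)$", "",
                                           ev$stream[is_meas | is_comm])

  if (any(is_meas)) {
    d_here <- drift[ev$hour_idx[is_meas]]
    pars <- vital_value_params()
    pos <- match(out$vital_kind[is_meas], pars$vital_kind)
    mu <- pars$center[pos] + (pars$target[pos] - pars$center[pos]) * d_here
    val <- rnorm_band(sum(is_meas), mu, pars$sd[pos], pars$lo[pos],
                      pars$hi[pos])
    out$value[is_meas] <- round(val, pars$digits[pos])
    out$avpu[is_meas] <- ifelse(d_here > 0.8, "V", "A")
    spo2 <- is_meas & out$vital_kind == "SpO2"
    out$oxygen_supplemental[spo2] <- drift[ev$hour_idx[spo2]] > 0.5
  }

  is_note <- ev$stream == "note_written"
  if (any(is_note)) {
    c_here <- concern[ev$hour_idx[is_note]]
    # tag intensity rises with concern through the same multiplier that
    # governs the note-writing rate, so zeroed multipliers give a true null
    tag_rate <- 0.8 *
      (1 + config$concern_multipliers[["note_written"]] * c_here)
    n_tags <- pmin(stats::rpois(sum(is_note), tag_rate), 5L)
    vocab <- note_concepts()
    tags <- vapply(n_tags, function(k) {
      if (k == 0L) "" else paste(sample(vocab, k), collapse = ";")
    }, character(1))
    out$note_concepts[is_note] <- ifelse(tags == "", NA_character_, tags)
  }

  out
}

# constant event hazard whose expected before-discharge event share over the
# drawn lengths of stay equals the requested fraction
event_hazard_rate <- function(los, event_fraction) {
  if (event_fraction >= 1) return(20)
  f <- function(lam) mean(1 - exp(-lam * los)) - event_fraction
  stats::uniroot(f, lower = 1e-8, upper = 20, tol = 1e-12)$root
}

empty_events <- function() {
  data.frame(encounter_id = character(), timestamp = as.POSIXct(character(),
             tz = "UTC"), event_type = character(), vital_kind = character(),
             value = numeric(), oxygen_supplemental = logical(),
             avpu = character(), note_concepts = character(),
             stringsAsFactors = FALSE)
}

#' Simulate a cohort of encounters, event streams and outcomes
#'
#' Draws encounter attributes (age, unit, admission time, length of stay,
#' hospice flag) and assigns composite outcomes by a constant event hazard:
#' every encounter draws an exponential event time with the single rate
#' chosen so that the expected fraction of encounters whose event falls
#' before discharge equals \code{event_fraction}. Constant hazard makes
#' elapsed time-at-risk uninformative about an imminent event, so in a null
#' cohort (multipliers and drift zeroed) even the mandatory temporal
#' features carry essentially no outcome signal. Each encounter's latent
#' trajectory and event stream are then generated.
#'
#' The generator is fully deterministic given \code{(config, config$seed)}:
#' running it twice yields byte-identical tables.
#'
#' @param config a [sim_config()]
#' @return list with data.frames \code{encounters}, \code{events},
#'   \code{outcomes}
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("config must be built with sim_config()", call. = FALSE)
  }
  set.seed(config$seed)
  n <- config$n_encounters

  enc_id <- sprintf("E%05d", seq_len(n))
  pat_id <- sprintf("P%05d", seq_len(n))
  age <- round(rnorm_band(n, config$age_distribution$mean,
                          config$age_distribution$sd,
                          config$age_distribution$min,
                          config$age_distribution$max), 1)
  unit <- sample(names(config$unit_mix), n, replace = TRUE,
                 prob = config$unit_mix)
  window <- as.POSIXct(config$admit_window, tz = "UTC")
  admit <- window[1] +
    round(stats::runif(n, 0, as.numeric(difftime(window[2], window[1],
                                                 units = "secs"))) / 60) * 60
  los <- exp(stats::rnorm(n, config$los_distribution$meanlog,
                          config$los_distribution$sdlog))
  los <- pmin(pmax(los, config$los_distribution$min),
              config$los_distribution$max)
  los <- round(los, 2)
  hospice <- stats::runif(n) < config$hospice_fraction

  if (config$event_fraction == 0) {
    has_event <- rep(FALSE, n)
    event_time <- rep(NA_real_, n)
  } else {
    lam <- event_hazard_rate(los, config$event_fraction)
    t_event <- stats::rexp(n, lam)
    has_event <- t_event <= los
    event_time <- rep(NA_real_, n)
    event_time[has_event] <- pmin(pmax(round(t_event[has_event], 2), 0.01),
                                  los[has_event])
  }
  component <- rep(NA_character_, n)
  component[has_event] <- sample(names(config$outcome_mix), sum(has_event),
                                 replace = TRUE, prob = config$outcome_mix)

  encounters <- data.frame(
    encounter_id = enc_id, patient_id = pat_id, age = age, unit_type = unit,
    admit_time = admit, discharge_time = admit + los * 3600,
    hospice_flag = hospice, stringsAsFactors = FALSE
  )

  ev_list <- vector("list", n)
  for (i in seq_len(n)) {
    traj <- simulate_latent_trajectory(event_time[i], los[i], config)
    ev_list[[i]] <- simulate_events(traj, encounters[i, ], config)
  }
  events <- data.table::rbindlist(ev_list)
  data.table::setDF(events)

  outcomes <- data.frame(
    encounter_id = enc_id[has_event],
    event_time = event_time[has_event],
    component = component[has_event],
    stringsAsFactors = FALSE
  )

  list(encounters = encounters, events = events, outcomes = outcomes)
}
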