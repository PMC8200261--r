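# Hourly MEWS/NEWS comparator series: last-observation-carried-forward vitals
# with a staleness limit, scored at the end of every inpatient hour.

# hourly LOCF of one quantity; obs = data.table(encounter_id, time_h, value)
locf_hourly <- function(grid, obs, staleness_hours) {
  if (nrow(obs) == 0L) {
    grid$value <- if (is.character(obs$value)) NA_character_ else NA_real_
    return(grid$value)
  }
  obs <- data.table::as.data.table(obs)
  data.table::setnames(obs, "time_h", "at")
  data.table::setorder(obs, encounter_id, at)
  # simultaneous observations of the same quantity: keep the last charted
  obs <- obs[, .(value = value[.N]), by = .(encounter_id, at)]
  q <- data.table::copy(grid)
  q[, at := patient_hour + 1]   # score uses data through the end of the hour
  joined <- obs[q, on = c("encounter_id", "at"), roll = staleness_hours]
  joined$value
}

#' Hourly MEWS/NEWS score series from raw events
#'
#' Vital values observed in the event stream are carried forward (most recent
#' observation no older than \code{staleness_hours}) onto the hourly grid and
#' scored with the bundled component tables. Like the CONCERN series, the
#' score computed from data through the end of hour t is stamped at patient
#' hour t + 1, so every score uses only strictly earlier observations. Hours
#' at which any required component has never been observed, or has gone
#' stale, carry a missing score; such hours are excluded from downstream
#' models rather than imputed.
#'
#' @param events clinical event table
#' @param encounters encounter table (defines the hourly grid)
#' @param system "MEWS" or "NEWS"
#' @param staleness_hours carry-forward limit (default 12)
#' @return data.frame: encounter_id, patient_hour, system, score, category
#' @export
comparator_score_series <- function(events, encounters,
                                    system = c("MEWS", "NEWS"),
                                    staleness_hours = 12) {
  system <- match.arg(system)
  grid <- hour_grid(encounters)[, .(encounter_id, admit_time, patient_hour)]

  meas <- events[events$event_type == "vital_measurement", , drop = FALSE]
  admit <- encounters$admit_time[match(meas$encounter_id,
                                       encounters$encounter_id)]
  meas_t <- hours_since(meas$timestamp, admit)

  get_kind <- function(kind, col = "value") {
    sel <- meas$vital_kind == kind & !is.na(meas[[col]])
    data.table::data.table(encounter_id = meas$encounter_id[sel],
                           time_h = meas_t[sel], value = meas[[col]][sel])
  }

  vit <- list(
    HR = locf_hourly(grid, get_kind("HR"), staleness_hours),
    RR = locf_hourly(grid, get_kind("RR"), staleness_hours),
    BP = locf_hourly(grid, get_kind("BP"), staleness_hours),
    Temp = locf_hourly(grid, get_kind("Temp"), staleness_hours),
    SpO2 = locf_hourly(grid, get_kind("SpO2"), staleness_hours)
  )
  # consciousness is assessed whenever any vital is measured
  avpu_obs <- data.table::data.table(
    encounter_id = meas$encounter_id[!is.na(meas$avpu)],
    time_h = meas_t[!is.na(meas$avpu)],
    value = meas$avpu[!is.na(meas$avpu)])
  avpu <- locf_hourly(grid, avpu_obs, staleness_hours)
  avpu[is.na(avpu)] <- NA_character_

  if (system == "MEWS") {
    score <- mews_total(hr = vit$HR, rr = vit$RR, sbp = vit$BP,
                        temp = vit$Temp, avpu = ifelse(is.na(avpu), "A", avpu))
    score[is.na(vit$HR) | is.na(vit$RR) | is.na(vit$BP) | is.na(vit$Temp)] <-
      NA_integer_
  } else {
    supp <- locf_hourly(grid, get_kind("SpO2", col = "oxygen_supplemental"),
                        staleness_hours)
    score <- news_total(rr = vit$RR, spo2 = vit$SpO2,
                        supp_o2 = !is.na(supp) & supp > 0,
                        temp = vit$Temp, sbp = vit$BP, hr = vit$HR,
                        avpu = ifelse(is.na(avpu), "A", avpu))
    score[is.na(vit$RR) | is.na(vit$SpO2) | is.na(vit$Temp) |
            is.na(vit$BP) | is.na(vit$HR)] <- NA_integer_
  }

  bands <- score_bands(system)
  out <- data.frame(
    encounter_id = grid$encounter_id,
    patient_hour = grid$patient_hour + 1L,
    system = system,
    score = as.numeric(score),
    category = as.character(categorize(pmax(score, 0), bands)),
    stringsAsFactors = FALSE
  )
  out$category[is.na(out$score)] <- NA_character_
  out
}

#' Hourly risk-score series for any scoring system
#'
#' Thin dispatcher: given a fitted reference scorer it produces the CONCERN
#' behavioral series from a feature matrix; given a system name it produces
#' the MEWS/NEWS comparator series from raw events.
#'
#' @param scorer_or_system a \code{concern_scorer} or "MEWS"/"NEWS"
#' @param features_or_events hourly feature matrix (CONCERN) or event table
#' @param encounters encounter table (comparators only)
#' @param ... passed through
#' @return data.frame: encounter_id, patient_hour, system, score, category
#' @export
score_series <- function(scorer_or_system, features_or_events,
                         encounters = NULL, ...) {
  if (inherits(scorer_or_system, "concern_scorer")) {
    concern_score_series(scorer_or_system, features_or_events, ...)
  } else {
    comparator_score_series(features_or_events, encounters,
                            system = scorer_or_system, ...)
  }
}
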