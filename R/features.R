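# Feature extraction: common/uncommon documentation hours and the hourly
# 55-column feature matrix (30 measurement + 21 note-content + 4 temporal).

# map raw clinical events onto the 15 base measurement-feature streams,
# deriving the two episode features from vital-measurement timestamps:
#   all_vitals_same_time : a 5-minute timestamp bin containing all five kinds
#   only_one_vital       : a vitals-taking episode (maximal run of vital
#                          measurements with gaps < 15 min) of one measurement
stream_events <- function(events) {
  ev <- data.table::as.data.table(events)
  base <- ev[event_type %in% c("vital_measurement", "vital_comment"),
             .(encounter_id, timestamp,
               stream = paste0(vital_kind,
                               ifelse(event_type == "vital_measurement",
                                      "_measurement", "_comment")))]
  other <- ev[event_type %in% c("prn_administered",
                                "scheduled_withheld", "note_written"),
              .(encounter_id, timestamp, stream = event_type)]

  meas <- ev[event_type == "vital_measurement",
             .(encounter_id, timestamp, vital_kind)]
  pseudo <- data.table::data.table(encounter_id = character(),
                                   timestamp = as.POSIXct(character(),
                                                          tz = "UTC"),
                                   stream = character())
  if (nrow(meas)) {
    data.table::setorder(meas, encounter_id, timestamp)
    meas[, bin5 := floor(as.numeric(timestamp) / 300)]
    all5 <- meas[, .(nk = data.table::uniqueN(vital_kind),
                     timestamp = min(timestamp)),
                 by = .(encounter_id, bin5)][nk == 5L]
    meas[, gap := c(Inf, diff(as.numeric(timestamp))),
         by = encounter_id]
    meas[, episode := cumsum(gap >= 900), by = encounter_id]
    only1 <- meas[, .(n = .N, timestamp = min(timestamp)),
                  by = .(encounter_id, episode)][n == 1L]
    pseudo <- rbind(
      all5[, .(encounter_id, timestamp, stream = "all_vitals_same_time")],
      only1[, .(encounter_id, timestamp, stream = "only_one_vital")]
    )
  }
  out <- rbind(base, other, pseudo)
  out[, hod := hour_of_day(timestamp)]
  out[]
}

#' Learn common documentation hours per base feature
#'
#' For each base measurement feature, the "common" hours of day are those
#' whose empirical share of events is at least \code{threshold} (default
#' 1/24, i.e. at or above uniform density); all remaining hours are
#' "uncommon". Features observed fewer than \code{min_events} times fall
#' back to the configured routine-vitals schedule, with a warning.
#'
#' @param events clinical event table
#' @param features base features to learn (default all 15)
#' @param threshold minimum hour-of-day share to call an hour common
#' @param min_events minimum training events required to learn empirically
#' @param fallback_hours hours used when a feature is too rare
#' @return object of class \code{common_time_profiles}: named list of integer
#'   hour vectors with a \code{source} attribute ("empirical"/"configured")
#' @export
learn_common_hours <- function(events, features = measurement_features(),
                               threshold = 1 / 24, min_events = 100,
                               fallback_hours = c(0L, 4L, 8L, 12L, 16L, 20L)) {
  se <- stream_events(events)
  profiles <- list()
  source <- character()
  for (f in features) {
    hods <- se$hod[se$stream == f]
    if (length(hods) < min_events) {
      warning(sprintf(
        "feature '%s' has only %d events (< %d); using configured schedule",
        f, length(hods), min_events), call. = FALSE)
      profiles[[f]] <- sort(as.integer(fallback_hours))
      source[f] <- "configured"
    } else {
      share <- tabulate(hods + 1L, nbins = 24) / length(hods)
      profiles[[f]] <- which(share >= threshold) - 1L
      source[f] <- "empirical"
    }
  }
  structure(profiles, source = source, threshold = threshold,
            class = "common_time_profiles")
}

#' @export
print.common_time_profiles <- function(x, ...) {
  cat("<common_time_profiles>", length(x), "features\n")
  for (f in names(x)) {
    cat(sprintf("  %-22s [%s] %s\n", f, attr(x, "source")[f],
                paste(x[[f]], collapse = ",")))
  }
  invisible(x)
}

# hourly grid (one row per inpatient hour per encounter) as a data.table
hour_grid <- function(encounters) {
  stay <- as.numeric(difftime(encounters$discharge_time,
                              encounters$admit_time, units = "hours"))
  n_hours <- pmax(1L, ceiling(stay))
  data.table::data.table(
    encounter_id = rep(encounters$encounter_id, n_hours),
    admit_time = rep(encounters$admit_time, n_hours),
    patient_hour = unlist(lapply(n_hours, function(k) seq_len(k) - 1L))
  )
}

# trailing window sums of hourly counts, adaptive at the start of the stay
roll_window <- function(grid, counts, value_cols, window_hours) {
  out <- merge(grid, counts, by = c("encounter_id", "patient_hour"),
               all.x = TRUE)
  for (v in value_cols) data.table::set(out, which(is.na(out[[v]])), v, 0)
  data.table::setorder(out, encounter_id, patient_hour)
  out[, (value_cols) := lapply(.SD, function(x)
    data.table::frollsum(x, n = pmin(seq_len(.N), window_hours),
                         adaptive = TRUE)),
    by = encounter_id, .SDcols = value_cols]
  out
}

#' Count note concepts over a trailing window
#'
#' One column per concept in the 21-label vocabulary; the value at a patient
#' hour is the number of notes in the trailing \code{window_hours} tagged
#' with that concept.
#'
#' @param events clinical event table (note events carry semicolon-joined
#'   concept tags)
#' @param encounters encounter table defining the hourly grid
#' @param window_hours trailing window length (default 12)
#' @return data.frame keyed by (encounter_id, patient_hour) with 21 columns
#' @export
count_note_concepts <- function(events, encounters, window_hours = 12) {
  notes <- events[events$event_type == "note_written" &
                    !is.na(events$note_concepts) &
                    nzchar(events$note_concepts), , drop = FALSE]
  note_cols <- feature_columns("note")
  grid <- hour_grid(encounters)

  if (nrow(notes)) {
    tags <- strsplit(notes$note_concepts, ";", fixed = TRUE)
    lens <- lengths(tags)
    long <- data.table::data.table(
      encounter_id = rep(notes$encounter_id, lens),
      timestamp = rep(notes$timestamp, lens),
      admit_time = rep(encounters$admit_time[
        match(notes$encounter_id, encounters$encounter_id)], lens),
      concept = unlist(tags)
    )
    unknown <- setdiff(unique(long$concept), note_concepts())
    if (length(unknown)) {
      stop(sprintf("unknown note concept label(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    long[, patient_hour := floor(hours_since(timestamp, admit_time))]
    counts <- data.table::dcast(
      long, encounter_id + patient_hour ~ paste0("note_", concept),
      fun.aggregate = length, value.var = "concept")
    missing <- setdiff(note_cols, names(counts))
    if (length(missing)) counts[, (missing) := 0L]
  } else {
    counts <- data.table::data.table(encounter_id = character(),
                                     patient_hour = integer())
    counts[, (note_cols) := integer(0)]
  }
  out <- roll_window(grid[, .(encounter_id, patient_hour)],
                     counts[, c("encounter_id", "patient_hour", note_cols),
                            with = FALSE],
                     note_cols, window_hours)
  data.table::setDF(out)
  out[, c("encounter_id", "patient_hour", note_cols)]
}

#' Build the hourly feature matrix
#'
#' One row per inpatient hour per encounter. The 15 base measurement features
#' are each split into a common-time and an uncommon-time count (30 columns)
#' according to the supplied profiles; note concepts contribute 21 count
#' columns; month, day of week (Monday = 0), hour of day and patient hour
#' (hours since admission) are the 4 temporal columns. All counts are
#' trailing \code{window_hours}-sums, closed on the right at the end of the
#' row's hour, so every value is computable in simulated real time.
#'
#' @param events clinical event table
#' @param encounters (filtered) encounter table
#' @param profiles a [learn_common_hours()] result
#' @param window_hours trailing window length in hours (default 12)
#' @return data.frame with encounter_id followed by the 55 feature columns
#' @export
build_hourly_features <- function(events, encounters, profiles,
                                  window_hours = 12) {
  assert_columns(encounters, c("encounter_id", "admit_time",
                               "discharge_time"), "encounter table")
  assert_columns(events, c("encounter_id", "timestamp", "event_type"),
                 "event table")
  orphans <- setdiff(unique(events$encounter_id), encounters$encounter_id)
  if (length(orphans)) {
    stop(sprintf("events reference unknown encounter(s): %s",
                 paste(utils::head(orphans, 10), collapse = ", ")),
         call. = FALSE)
  }
  missing_prof <- setdiff(measurement_features(), names(profiles))
  if (length(missing_prof)) {
    stop(sprintf("profiles missing for feature(s): %s",
                 paste(missing_prof, collapse = ", ")), call. = FALSE)
  }

  grid <- hour_grid(encounters)
  se <- stream_events(events)
  se <- merge(se,
              data.table::data.table(
                encounter_id = encounters$encounter_id,
                admit_time = encounters$admit_time),
              by = "encounter_id")
  se[, patient_hour := floor(hours_since(timestamp, admit_time))]
  feats <- measurement_features()
  lookup <- vapply(feats, function(f) 0:23 %in% profiles[[f]], logical(24))
  common <- lookup[cbind(se$hod + 1L, match(se$stream, feats))]
  se[, col := paste0(stream, ifelse(common, "_common", "_uncommon"))]

  meas_cols <- feature_columns("measurement")
  counts <- data.table::dcast(se, encounter_id + patient_hour ~ col,
                              fun.aggregate = length, value.var = "col")
  missing <- setdiff(meas_cols, names(counts))
  if (length(missing)) counts[, (missing) := 0L]
  meas <- roll_window(grid[, .(encounter_id, patient_hour)],
                      counts[, c("encounter_id", "patient_hour", meas_cols),
                             with = FALSE],
                      meas_cols, window_hours)

  notes <- count_note_concepts(events, encounters, window_hours)

  out <- merge(meas, data.table::as.data.table(notes),
               by = c("encounter_id", "patient_hour"))
  out <- merge(out, grid, by = c("encounter_id", "patient_hour"))
  wall <- out$admit_time + out$patient_hour * 3600
  out[, month := as.integer(format(wall, "%m", tz = "UTC"))]
  out[, day_of_week := (as.integer(format(wall, "%u", tz = "UTC")) - 1L)]
  out[, hour := hour_of_day(wall)]
  out[, admit_time := NULL]
  data.table::setorder(out, encounter_id, patient_hour)
  data.table::setcolorder(out, c("encounter_id", meas_cols,
                                 feature_columns("note"),
                                 "month", "day_of_week", "hour",
                                 "patient_hour"))
  data.table::setDF(out)
  out
}
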