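#' Feature and event vocabularies
#'
#' Fixed vocabularies shared by the simulator, the feature extractor and the
#' scorers: the five vital-sign kinds, the fifteen base measurement features
#' (each later expanded into a common-time and an uncommon-time column), the
#' 21 nursing-note concept labels, and the clinical event types.
#'
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
vital_kinds <- function() c("HR", "RR", "BP", "Temp", "SpO2")

#' @rdname vocabularies
#' @export
event_types <- function() {
  c("vital_measurement", "vital_comment", "prn_administered",
    "scheduled_withheld", "note_written")
}

#' @rdname vocabularies
#' @export
outcome_components <- function() {
  c("mortality", "cardiac_arrest", "icu_transfer", "rapid_response", "sepsis")
}

#' The fifteen base measurement features, in canonical column order.
#'
#' Five per-vital measurement counts, the all-five-vitals-at-the-same-time
#' episode count, the single-vital episode count, five per-vital flowsheet
#' comment counts, PRN administrations, withheld scheduled medications and
#' nursing notes written. Every one is clustered into common/uncommon
#' documentation hours and aggregated over a trailing window.
#'
#' @return character vector of length 15
#' @export
measurement_features <- function() {
  c(paste0(vital_kinds(), "_measurement"),
    "all_vitals_same_time", "only_one_vital",
    paste0(vital_kinds(), "_comment"),
    "prn_administered", "scheduled_withheld", "note_written")
}

#' The 21-label nursing-note concept vocabulary.
#'
#' Concept tags carried by simulated note events; real deployments would
#' populate these with an NLP pipeline, which is out of scope here.
#'
#' @return character vector of length 21
#' @export
note_concepts <- function() {
  c("abdominal_pain", "abnormal_heart_rhythm", "abnormal_mental_state",
    "abnormal_respirations", "abnormal_temperature", "back_pain",
    "chest_pain", "communication_problem", "infection_diagnosis",
    "circulation_deficit", "fall_risk", "fluid_volume_alteration",
    "general_concern", "headache", "renal_function_concern",
    "infection_medication", "monitoring", "mood_disorder",
    "musculoskeletal_pain", "pain_level", "violence_gesture")
}

#' Column names of the hourly feature matrix, by group
#'
#' @param group one of "measurement" (30 columns: 15 base features x
#'   common/uncommon), "note" (21 concept-count columns) or "temporal"
#'   (month, day_of_week, hour, patient_hour).
#' @return character vector of column names
#' @export
feature_columns <- function(group = c("measurement", "note", "temporal")) {
  group <- match.arg(group)
  switch(group,
    measurement = as.vector(t(outer(measurement_features(),
                                    c("_common", "_uncommon"), paste0))),
    note = paste0("note_", note_concepts()),
    temporal = c("month", "day_of_week", "hour", "patient_hour"))
}

#' All 55 model feature columns in canonical order
#' @return character vector of length 55
#' @export
all_feature_columns <- function() {
  c(feature_columns("measurement"), feature_columns("note"),
    feature_columns("temporal"))
}

# event stream names used internally: one per Poisson-generated stream
poisson_streams <- function() {
  setdiff(measurement_features(), c("all_vitals_same_time", "only_one_vital"))
}
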