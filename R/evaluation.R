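# Score-outcome evaluation: composite endpoint, counting-process records for
# the time-varying-covariate Cox model, and the partial-likelihood fit.

#' First composite event per encounter
#'
#' The endpoint is the first occurrence of any composite component
#' (mortality, cardiac arrest, unanticipated ICU transfer, rapid response,
#' sepsis). Encounters with no component are right-censored at discharge.
#'
#' @param outcomes outcome table (encounter_id, event_time, component);
#'   multiple components per encounter are allowed, only the earliest is used
#' @param encounters encounter table (provides discharge censoring times)
#' @return data.frame: encounter_id, event_time (NA if censored),
#'   censor_time, end_time = min(event, censor), has_event
#' @export
composite_first_event <- function(outcomes, encounters) {
  assert_columns(outcomes, c("encounter_id", "event_time"), "outcome table")
  assert_columns(encounters, c("encounter_id", "admit_time",
                               "discharge_time"), "encounter table")
  censor <- as.numeric(difftime(encounters$discharge_time,
                                encounters$admit_time, units = "hours"))
  first <- tapply(outcomes$event_time, outcomes$encounter_id, min)
  ev <- as.numeric(first[match(encounters$encounter_id, names(first))])
  bad <- !is.na(ev) & ev > censor
  if (any(bad)) {
    stop(sprintf("event after discharge for encounter(s): %s",
                 paste(encounters$encounter_id[bad], collapse = ", ")),
         call. = FALSE)
  }
  data.frame(
    encounter_id = encounters$encounter_id,
    event_time = ev,
    censor_time = censor,
    end_time = pmin(ev, censor, na.rm = TRUE),
    has_event = !is.na(ev),
    stringsAsFactors = FALSE
  )
}

#' Counting-process records from hourly category series
#'
#' Converts hourly low/moderate/high category series (one or several scoring
#' systems) into (start, stop] intervals with one record per maximal run of a
#' constant covariate vector. Hours with a missing category in any requested
#' system are excluded; at-risk time ends at the first event or at discharge,
#' and the event is attached to the interval containing it. Covariates are
#' moderate/high indicators per system, with the low band as reference.
#'
#' @param scores long score table (encounter_id, patient_hour, system,
#'   category) as produced by the scoring functions
#' @param first_events result of [composite_first_event()]
#' @param systems systems to include (default: all present)
#' @return data.frame: encounter_id, start, stop, event, plus one indicator
#'   column \code{<system>_moderate} / \code{<system>_high} per system
#' @export
to_counting_process <- function(scores, first_events, systems = NULL) {
  sc <- data.table::as.data.table(scores)
  if (is.null(systems)) systems <- unique(sc$system)
  sc <- sc[system %in% systems]

  wide <- data.table::dcast(sc, encounter_id + patient_hour ~ system,
                            value.var = "category")
  fe <- first_events[match(wide$encounter_id, first_events$encounter_id), ]
  wide <- wide[wide$patient_hour < fe$end_time]
  fe <- first_events[match(wide$encounter_id, first_events$encounter_id), ]

  complete <- rowSums(is.na(wide[, systems, with = FALSE])) == 0
  wide <- wide[complete]
  fe <- fe[complete, , drop = FALSE]
  if (nrow(wide) == 0L) stop("no scoreable patient-hours", call. = FALSE)

  ind_cols <- character(0)
  for (s in systems) {
    cat_s <- wide[[s]]
    wide[, (paste0(tolower(s), "_moderate")) := as.integer(cat_s == "moderate")]
    wide[, (paste0(tolower(s), "_high")) := as.integer(cat_s == "high")]
    ind_cols <- c(ind_cols, paste0(tolower(s), c("_moderate", "_high")))
  }
  key <- do.call(paste, c(wide[, systems, with = FALSE], sep = "|"))
  wide[, key := key]
  wide[, end_time := fe$end_time]
  wide[, ev_time := fe$event_time]
  data.table::setorder(wide, encounter_id, patient_hour)
  # new interval at every category change or hour gap
  wide[, run := cumsum(c(1L, (key[-1] != key[-.N]) |
                           (diff(patient_hour) != 1L))),
       by = encounter_id]
  rec <- wide[, c(.(start = patient_hour[1],
                    stop = min(patient_hour[.N] + 1, end_time[1]),
                    event = as.integer(!is.na(ev_time[1]) &
                                         ev_time[1] > patient_hour[1] &
                                         ev_time[1] <= patient_hour[.N] + 1)),
                  lapply(.SD, data.table::first)),
              by = .(encounter_id, run), .SDcols = ind_cols]
  rec[, run := NULL]
  if (any(rec$stop <= rec$start)) {
    stop("degenerate interval construction (stop <= start)", call. = FALSE)
  }
  data.table::setDF(rec)
  rec
}

#' Fit the time-varying-covariate Cox proportional-hazards model
#'
#' Partial-likelihood fit (Efron approximation for ties) of the composite
#' endpoint on the counting-process records, with low-risk bands as the
#' reference. Constant covariates are dropped with a warning. Confidence
#' intervals are Wald on the log hazard-ratio scale at 95%.
#'
#' @param records result of [to_counting_process()]
#' @param covariates covariate columns to use (default: all indicator
#'   columns present)
#' @param min_events minimum number of events required (default 10)
#' @return data.frame of class \code{hazard_model_result}: covariate, hr,
#'   ci_low, ci_high, p; attributes n_intervals, n_events, ties
#' @export
fit_time_varying_cox <- function(records, covariates = NULL,
                                 min_events = 10L) {
  if (is.null(covariates)) {
    covariates <- setdiff(names(records),
                          c("encounter_id", "start", "stop", "event"))
  }
  n_events <- sum(records$event)
  if (n_events < min_events) {
    stop(sprintf("only %d events (< %d); refusing to fit", n_events,
                 min_events), call. = FALSE)
  }
  keep <- covariates[vapply(covariates,
                            function(v) length(unique(records[[v]])) > 1,
                            logical(1))]
  dropped <- setdiff(covariates, keep)
  if (length(dropped)) {
    warning(sprintf("dropping constant covariate(s): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  if (!length(keep)) stop("no non-constant covariates", call. = FALSE)

  f <- stats::as.formula(paste("survival::Surv(start, stop, event) ~",
                               paste(keep, collapse = " + ")))
  # with very large true hazard contrasts the cold-started Newton iteration
  # can overflow even though the maximum is finite; retry from a crude
  # per-covariate rate-ratio warm start before giving up
  warm <- vapply(keep, function(v) {
    len <- records$stop - records$start
    on <- records[[v]] > 0
    ref <- rowSums(as.matrix(records[, keep, drop = FALSE])) == 0
    r_on <- (sum(records$event[on]) + 0.5) / max(sum(len[on]), 1e-9)
    r_ref <- (sum(records$event[ref]) + 0.5) / max(sum(len[ref]), 1e-9)
    min(max(log(r_on / r_ref), -8), 8)
  }, numeric(1))
  fit <- tryCatch(
    survival::coxph(f, data = records, ties = "efron"),
    error = function(e1) {
      tryCatch(
        survival::coxph(f, data = records, ties = "efron", init = warm,
                        control = survival::coxph.control(iter.max = 100)),
        error = function(e2) {
          stop(sprintf(
            "Cox partial-likelihood fit failed (%s); a covariate level may
perfectly separate events from non-events at this sample size",
            conditionMessage(e2)), call. = FALSE)
        })
    })
  if (!is.null(fit$info) && any(grepl("did not converge", fit$info))) {
    stop("Cox partial-likelihood fit did not converge", call. = FALSE)
  }
  sm <- summary(fit)
  out <- data.frame(
    covariate = rownames(sm$coefficients),
    hr = unname(sm$coefficients[, "exp(coef)"]),
    ci_low = unname(sm$conf.int[, "lower .95"]),
    ci_high = unname(sm$conf.int[, "upper .95"]),
    p = unname(sm$coefficients[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_intervals") <- nrow(records)
  attr(out, "n_events") <- n_events
  attr(out, "ties") <- "efron"
  attr(out, "coef") <- stats::coef(fit)
  attr(out, "se") <- sqrt(diag(fit$var))
  class(out) <- c("hazard_model_result", "data.frame")
  out
}

#' @export
print.hazard_model_result <- function(x, ...) {
  cat("<hazard_model_result>", attr(x, "n_events"), "events over",
      attr(x, "n_intervals"), "intervals (ties:", attr(x, "ties"), ")\n")
  print.data.frame(cbind(x[, "covariate", drop = FALSE],
                         round(x[, c("hr", "ci_low", "ci_high")], 3),
                         p = signif(x$p, 3)))
  invisible(x)
}
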