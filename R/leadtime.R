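# Lead-time likelihood-ratio statistic
#
# L(x, h) = P(x | patient has an event h hours in the future) /
#           P(x | patient does not have an event h hours in the future)
#
# estimated per scoring system over a grid of horizons from hourly category
# series. Separation of log L from 0 at large h indicates early warning.

#' Compute lead-time likelihood-ratio curves
#'
#' For each horizon \code{h}, the numerator stratum contains the
#' patient-hours whose encounter has its first composite event exactly in
#' hour bin \code{t + h} (the default exact-horizon convention; the
#' "cumulative" alternative counts an event anywhere in \code{(t, t + h]}),
#' and the denominator stratum the patient-hours verified event-free through
#' \code{t + h}. Hours whose encounter is censored within \code{h} hours are
#' excluded (their status at \code{t + h} is unknown), as are hours with a
#' missing category.
#'
#' Both conditional category tables are shrunk additively before the ratio:
#' each level's frequency becomes \code{(p + k/s) / (1 + 3k/s)} where
#' \code{k} is the smoothing constant and \code{s} the smaller stratum size.
#' For balanced strata this is classical add-k smoothing; the common shrink
#' keeps L finite, exactly inverts under event/non-event relabeling, and
#' yields L = 1 for a level observed in neither stratum.
#'
#' @param scores long score table (encounter_id, patient_hour, system,
#'   category)
#' @param first_events result of [composite_first_event()]
#' @param horizons integer vector of horizons in hours (default 1:48)
#' @param smoothing add-k smoothing constant k (default 0.5)
#' @param convention "exact" (event exactly h hours ahead) or "cumulative"
#'   (event within the next h hours)
#' @return data.frame of class \code{lead_time_curve}: system, level, h,
#'   l, log_lr, n_num, n_den (stratum sizes), num_count, den_count
#' @export
compute_lead_time_lr <- function(scores, first_events, horizons = 1:48,
                                 smoothing = 0.5,
                                 convention = c("exact", "cumulative")) {
  convention <- match.arg(convention)
  levels3 <- c("low", "moderate", "high")
  sc <- data.table::as.data.table(scores)
  fe <- first_events[match(sc$encounter_id, first_events$encounter_id), ]
  sc[, `:=`(ev_bin = floor(fe$event_time), has_event = fe$has_event,
            censor_time = fe$censor_time, end_time = fe$end_time)]
  sc <- sc[!is.na(category) & patient_hour < end_time]

  out <- list()
  for (sys in unique(sc$system)) {
    d <- sc[system == sys]
    for (h in horizons) {
      if (convention == "exact") {
        num <- d$has_event & (d$ev_bin - d$patient_hour) == h
      } else {
        gap <- d$ev_bin - d$patient_hour
        num <- d$has_event & gap >= 1 & gap <= h
      }
      den <- (d$has_event & d$ev_bin > d$patient_hour + h) |
        (!d$has_event & d$censor_time >= d$patient_hour + h + 1)
      n_num <- sum(num)
      n_den <- sum(den)
      if (n_num == 0L || n_den == 0L) {
        stop(sprintf("empty stratum at horizon h = %d for system %s", h,
                     sys), call. = FALSE)
      }
      num_count <- as.integer(table(factor(d$category[num],
                                           levels = levels3)))
      den_count <- as.integer(table(factor(d$category[den],
                                           levels = levels3)))
      shrink <- smoothing / min(n_num, n_den)
      p_num <- (num_count / n_num + shrink) / (1 + 3 * shrink)
      p_den <- (den_count / n_den + shrink) / (1 + 3 * shrink)
      l <- p_num / p_den
      out[[length(out) + 1L]] <- data.frame(
        system = sys, level = levels3, h = h, l = l, log_lr = log(l),
        n_num = n_num, n_den = n_den, num_count = num_count,
        den_count = den_count, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "smoothing") <- smoothing
  attr(res, "convention") <- convention
  class(res) <- c("lead_time_curve", "data.frame")
  res
}

#' Warning horizon of a lead-time curve
#'
#' The largest horizon at which a score level still separates events from
#' non-events: max h with log L(level, h) > threshold (0 when the level
#' never separates). Scores whose behavioral signal activates long before
#' the event retain separation at much larger h than physiology-based
#' comparators.
#'
#' @param curves result of [compute_lead_time_lr()]
#' @param level score level examined (default "high")
#' @param threshold log likelihood-ratio threshold (default log(1.5))
#' @return named numeric vector: warning horizon in hours per system
#' @export
lead_time_horizon <- function(curves, level = "high",
                              threshold = log(1.5)) {
  systems <- unique(curves$system)
  vapply(systems, function(sys) {
    d <- curves[curves$system == sys & curves$level == level, ]
    hit <- d$h[is.finite(d$log_lr) & d$log_lr > threshold]
    if (length(hit)) max(hit) else 0
  }, numeric(1))
}
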