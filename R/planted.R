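#' Simulate encounters with a planted hazard-rate multiplier
#'
#' A generative oracle for the time-varying Cox fit: each encounter's hourly
#' risk category follows a two-state Markov chain between "low" and "high",
#' and the event hazard is piecewise-constant,
#' \code{baseline_hazard * hazard_ratio^(state == high)}. The partial
#' likelihood estimate of the high-state log hazard ratio should recover
#' \code{log(hazard_ratio)} as the number of encounters grows.
#'
#' @param n_encounters number of encounters
#' @param hazard_ratio planted multiplicative hazard of the high state
#' @param baseline_hazard events/hour in the low state (default 0.002)
#' @param p_low_high,p_high_low hourly Markov transition probabilities
#'   (defaults give a stationary high-state share of 0.25)
#' @param max_hours administrative censoring time (default 240)
#' @param seed integer seed
#' @return list with \code{scores} (encounter_id, patient_hour, system =
#'   "planted", category in low/high) and \code{first_events} (encounter_id,
#'   event_time, censor_time, end_time, has_event), the format consumed by
#'   [to_counting_process()]
#' @export
simulate_planted_hazard <- function(n_encounters, hazard_ratio,
                                    baseline_hazard = 0.002,
                                    p_low_high = 0.05, p_high_low = 0.15,
                                    max_hours = 240, seed = 1L) {
  if (hazard_ratio <= 0) stop("hazard_ratio must be positive", call. = FALSE)
  set.seed(seed)
  n <- as.integer(n_encounters)
  H <- as.integer(max_hours)
  pi_high <- p_low_high / (p_low_high + p_high_low)

  # state matrix n x H, simulated column-by-column (vectorized over encounters)
  state <- matrix(FALSE, n, H)
  state[, 1] <- stats::runif(n) < pi_high
  if (H > 1) {
    for (t in 2:H) {
      u <- stats::runif(n)
      state[, t] <- ifelse(state[, t - 1], u >= p_high_low, u < p_low_high)
    }
  }
  haz <- baseline_hazard * ifelse(state, hazard_ratio, 1)
  p_event <- 1 - exp(-haz)
  u <- matrix(stats::runif(n * H), n, H)
  hit <- u < p_event
  first_hit <- apply(hit, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)

  has_event <- !is.na(first_hit)
  # event placed uniformly within its hour
  event_time <- ifelse(has_event, first_hit - 1 + stats::runif(n), NA_real_)
  end_time <- ifelse(has_event, event_time, H)
  n_hours <- pmax(1L, ceiling(end_time))

  enc_id <- sprintf("K%05d", seq_len(n))
  idx <- rep.int(seq_len(n), n_hours)
  hr_seq <- unlist(lapply(n_hours, function(k) seq_len(k) - 1L))
  cat <- ifelse(state[cbind(idx, hr_seq + 1L)], "high", "low")

  scores <- data.frame(
    encounter_id = enc_id[idx], patient_hour = hr_seq, system = "planted",
    score = as.numeric(cat == "high"), category = cat,
    stringsAsFactors = FALSE
  )
  first_events <- data.frame(
    encounter_id = enc_id,
    event_time = event_time,
    censor_time = rep(as.numeric(H), n),
    end_time = end_time,
    has_event = has_event,
    stringsAsFactors = FALSE
  )
  list(scores = scores, first_events = first_events)
}
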