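# Independent brute-force oracles, deliberately written as naive rescans so
# they share no code with the package implementation.

# full-rescan window-sum oracle for the hourly feature matrix of a single
# encounter: loops over rows and events, re-deriving episode pseudo-events
# with plain loops
oracle_features <- function(events, admit, n_hours, profiles,
                            window_hours = 12) {
  h_of <- function(ts) as.numeric(difftime(ts, admit, units = "hours"))
  ev <- events[order(events$timestamp), , drop = FALSE]
  inst <- data.frame(time = numeric(0), stream = character(0))
  for (i in seq_len(nrow(ev))) {
    s <- switch(ev$event_type[i],
                vital_measurement = paste0(ev$vital_kind[i], "_measurement"),
                vital_comment = paste0(ev$vital_kind[i], "_comment"),
                ev$event_type[i])
    inst <- rbind(inst, data.frame(time = h_of(ev$timestamp[i]), stream = s))
  }
  meas <- ev[ev$event_type == "vital_measurement", , drop = FALSE]
  if (nrow(meas)) {
    bins <- unique(floor(as.numeric(meas$timestamp) / 300))
    for (b in bins) {
      in_bin <- meas[floor(as.numeric(meas$timestamp) / 300) == b, ]
      if (length(unique(in_bin$vital_kind)) == 5) {
        inst <- rbind(inst, data.frame(
          time = min(h_of(in_bin$timestamp)),
          stream = "all_vitals_same_time"))
      }
    }
    tm <- sort(as.numeric(meas$timestamp))
    runs <- list()
    cur <- c(1)
    for (i in seq_len(length(tm) - 1)[length(tm) > 1]) {
      if (tm[i + 1] - tm[i] < 900) cur <- c(cur, i + 1)
      else { runs[[length(runs) + 1]] <- cur; cur <- c(i + 1) }
    }
    runs[[length(runs) + 1]] <- cur
    for (r in runs) {
      if (length(r) == 1) {
        inst <- rbind(inst, data.frame(
          time = (tm[r[1]] - as.numeric(admit)) / 3600,
          stream = "only_one_vital"))
      }
    }
  }
  inst$hod <- (hour_of(admit) + floor(inst$time)) %% 24

  out <- matrix(0L, n_hours,
                length(feature_columns("measurement")) +
                  length(feature_columns("note")),
                dimnames = list(NULL, c(feature_columns("measurement"),
                                        feature_columns("note"))))
  for (t in seq_len(n_hours) - 1) {
    lo <- max(0, t - window_hours + 1)
    for (j in seq_len(nrow(inst))) {
      bin <- floor(inst$time[j])
      if (bin >= lo && bin <= t) {
        suffix <- if (inst$hod[j] %in% profiles[[inst$stream[j]]])
          "_common" else "_uncommon"
        cn <- paste0(inst$stream[j], suffix)
        out[t + 1, cn] <- out[t + 1, cn] + 1L
      }
    }
    notes <- ev[ev$event_type == "note_written" &
                  !is.na(ev$note_concepts), , drop = FALSE]
    for (j in seq_len(nrow(notes))) {
      bin <- floor(h_of(notes$timestamp[j]))
      if (bin >= lo && bin <= t) {
        for (tag in strsplit(notes$note_concepts[j], ";")[[1]]) {
          cn <- paste0("note_", tag)
          out[t + 1, cn] <- out[t + 1, cn] + 1L
        }
      }
    }
  }
  out
}

hour_of <- function(ts) as.integer(format(ts, "%H", tz = "UTC"))

# independently hand-typed MEWS bands (Subbe 2001), closed integer bands
oracle_mews <- function(hr, rr, sbp, temp, avpu = "A") {
  p_sbp <- ifelse(sbp < 71, 3, ifelse(sbp < 81, 2, ifelse(sbp < 101, 1,
            ifelse(sbp < 200, 0, 2))))
  p_hr <- ifelse(hr < 41, 2, ifelse(hr < 51, 1, ifelse(hr < 101, 0,
           ifelse(hr < 111, 1, ifelse(hr < 130, 2, 3)))))
  p_rr <- ifelse(rr < 9, 2, ifelse(rr < 15, 0, ifelse(rr < 21, 1,
           ifelse(rr < 30, 2, 3))))
  p_t <- ifelse(temp < 35, 2, ifelse(temp < 38.5, 0, 2))
  p_a <- c(A = 0, V = 1, P = 2, U = 3)[avpu]
  p_sbp + p_hr + p_rr + p_t + unname(p_a)
}

# independently hand-typed NEWS bands (RCP 2012)
oracle_news <- function(rr, spo2, supp, temp, sbp, hr, avpu = "A") {
  p_rr <- ifelse(rr < 9, 3, ifelse(rr < 12, 1, ifelse(rr < 21, 0,
           ifelse(rr < 25, 2, 3))))
  p_sp <- ifelse(spo2 < 92, 3, ifelse(spo2 < 94, 2, ifelse(spo2 < 96, 1, 0)))
  p_o2 <- ifelse(supp, 2, 0)
  p_t <- ifelse(temp < 35.1, 3, ifelse(temp < 36.1, 1, ifelse(temp < 38.1, 0,
          ifelse(temp < 39.1, 1, 2))))
  p_bp <- ifelse(sbp < 91, 3, ifelse(sbp < 101, 2, ifelse(sbp < 111, 1,
           ifelse(sbp < 220, 0, 3))))
  p_hr <- ifelse(hr < 41, 3, ifelse(hr < 51, 1, ifelse(hr < 91, 0,
           ifelse(hr < 111, 1, ifelse(hr < 131, 2, 3)))))
  p_a <- ifelse(avpu == "A", 0, 3)
  p_rr + p_sp + p_o2 + p_t + p_bp + p_hr + p_a
}
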