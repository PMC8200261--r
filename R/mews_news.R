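# MEWS and NEWS comparator scores: per-component integer point lookups from
# the standard published tables bundled under inst/extdata, plus the
# low/moderate/high categorical bands.

points_table_env <- new.env(parent = emptyenv())

read_points_table <- function(system = c("MEWS", "NEWS")) {
  system <- match.arg(system)
  key <- paste0("tab_", system)
  if (!is.null(points_table_env[[key]])) return(points_table_env[[key]])
  path <- system.file("extdata",
                      if (system == "MEWS") "mews_points.csv"
                      else "news_points.csv",
                      package = "concernews")
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  tab$lower <- as.numeric(tab$lower)
  tab$upper <- as.numeric(tab$upper)
  points_table_env[[key]] <- tab
  tab
}

#' Bundled MEWS / NEWS component point tables
#' @return data.frame with columns component, lower, upper (half-open
#'   interval) and points
#' @export
mews_points_table <- function() read_points_table("MEWS")

#' @rdname mews_points_table
#' @export
news_points_table <- function() read_points_table("NEWS")

component_points <- function(tab, component, values) {
  rows <- tab[tab$component == component, , drop = FALSE]
  rows <- rows[order(rows$lower), , drop = FALSE]
  idx <- findInterval(values, rows$lower[-1]) + 1L
  out <- rows$points[idx]
  out[is.na(values)] <- NA_integer_
  out
}

avpu_code <- function(avpu) {
  code <- match(toupper(as.character(avpu)), c("A", "V", "P", "U")) - 1L
  code
}

#' Total MEWS from last-observed vitals
#'
#' Sum of per-component integer points (systolic blood pressure, heart rate,
#' respiratory rate, temperature, AVPU) from the bundled table. Any missing
#' component yields \code{NA}: the score is undefined for that hour.
#'
#' @param hr,rr,sbp,temp numeric vitals (systolic blood pressure in mmHg)
#' @param avpu consciousness, one of "A","V","P","U" (default alert)
#' @return integer vector of total scores in 0..14
#' @export
mews_total <- function(hr, rr, sbp, temp, avpu = "A") {
  tab <- mews_points_table()
  n <- max(length(hr), length(rr), length(sbp), length(temp), length(avpu))
  as.integer(component_points(tab, "hr", rep_len(hr, n))) +
    component_points(tab, "rr", rep_len(rr, n)) +
    component_points(tab, "sbp", rep_len(sbp, n)) +
    component_points(tab, "temp", rep_len(temp, n)) +
    component_points(tab, "avpu", avpu_code(rep_len(avpu, n)))
}

#' Total NEWS from last-observed vitals
#'
#' Sum of the seven NEWS component points (respiratory rate, SpO2,
#' supplemental oxygen, temperature, systolic blood pressure, heart rate,
#' consciousness). Any missing component yields \code{NA}.
#'
#' @param rr,spo2,temp,sbp,hr numeric vitals
#' @param supp_o2 logical, on supplemental oxygen
#' @param avpu consciousness, one of "A","V","P","U"
#' @return integer vector of total scores in 0..20
#' @export
news_total <- function(rr, spo2, supp_o2, temp, sbp, hr, avpu = "A") {
  tab <- news_points_table()
  n <- max(length(rr), length(spo2), length(supp_o2), length(temp),
           length(sbp), length(hr), length(avpu))
  as.integer(component_points(tab, "rr", rep_len(rr, n))) +
    component_points(tab, "spo2", rep_len(spo2, n)) +
    component_points(tab, "supp_o2", as.numeric(rep_len(supp_o2, n))) +
    component_points(tab, "temp", rep_len(temp, n)) +
    component_points(tab, "sbp", rep_len(sbp, n)) +
    component_points(tab, "hr", rep_len(hr, n)) +
    component_points(tab, "avpu", avpu_code(rep_len(avpu, n)))
}

#' Risk-band definitions
#'
#' MEWS: low 0-2, moderate 3-4, high 5+. NEWS: low 0-3, moderate 4-6,
#' high 7+. CONCERN bands are continuous cutpoints taken from a fitted
#' reference scorer (training-distribution quantiles); its low/moderate/high
#' categories alias the green/yellow/red display colors.
#'
#' @param system "MEWS", "NEWS" or "CONCERN"
#' @param cutpoints length-2 increasing numeric vector; scores >= cutpoints[1]
#'   are moderate and >= cutpoints[2] high. Required for CONCERN; defaults to
#'   the published integer bands for MEWS/NEWS.
#' @return object of class \code{score_bands}
#' @export
score_bands <- function(system = c("MEWS", "NEWS", "CONCERN"),
                        cutpoints = NULL) {
  system <- match.arg(system)
  if (is.null(cutpoints)) {
    cutpoints <- switch(system,
      MEWS = c(3, 5),
      NEWS = c(4, 7),
      CONCERN = stop("CONCERN bands need explicit cutpoints", call. = FALSE))
  }
  if (length(cutpoints) != 2 || diff(cutpoints) <= 0) {
    stop("cutpoints must be two strictly increasing values", call. = FALSE)
  }
  structure(list(system = system, cutpoints = as.numeric(cutpoints)),
            class = "score_bands")
}

#' Map scores to low/moderate/high categories
#'
#' @param score numeric score vector (NA passes through as NA)
#' @param bands a [score_bands()] object
#' @return factor with levels low < moderate < high
#' @export
categorize <- function(score, bands) {
  stopifnot(inherits(bands, "score_bands"))
  if (any(score < 0, na.rm = TRUE)) {
    stop("scores must be nonnegative", call. = FALSE)
  }
  lab <- ifelse(score >= bands$cutpoints[2], "high",
                ifelse(score >= bands$cutpoints[1], "moderate", "low"))
  factor(lab, levels = c("low", "moderate", "high"))
}

#' @export
print.score_bands <- function(x, ...) {
  cat(sprintf("<score_bands> %s: low < %g <= moderate < %g <= high\n",
              x$system, x$cutpoints[1], x$cutpoints[2]))
  invisible(x)
}
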