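#' Apply cohort inclusion filters
#'
#' Retains encounters with a unit stay of more than 24 hours, patient age of
#' at least 18 years, no hospice/palliative flag, and a total stay of at most
#' 60 days. Boundary semantics are literal: exactly 24 hours is excluded,
#' exactly 60 days is retained, exactly 18 years is retained.
#'
#' @param encounters encounter table with columns \code{encounter_id},
#'   \code{age}, \code{admit_time}, \code{discharge_time},
#'   \code{hospice_flag}
#' @return the filtered encounter table, with attribute
#'   \code{exclusion_tally}: named integer counts of encounters violating
#'   each rule (an encounter violating several rules is counted under each)
#'   plus the number excluded overall
#' @export
apply_inclusion_filters <- function(encounters) {
  assert_columns(encounters,
                 c("encounter_id", "age", "admit_time", "discharge_time",
                   "hospice_flag"), "encounter table")
  stay_h <- as.numeric(difftime(encounters$discharge_time,
                                encounters$admit_time, units = "hours"))
  viol <- cbind(
    under_18 = encounters$age < 18,
    stay_le_24h = stay_h <= 24,
    hospice = as.logical(encounters$hospice_flag),
    stay_gt_60d = stay_h > 60 * 24
  )
  keep <- rowSums(viol) == 0
  tally <- c(colSums(viol), excluded = sum(!keep))
  out <- encounters[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusion_tally") <- as.integer(tally)
  names(attr(out, "exclusion_tally")) <- names(tally)
  out
}

#' Retrieve the per-rule exclusion tally of a filtered encounter table
#' @param filtered result of [apply_inclusion_filters()]
#' @return named integer vector
#' @export
exclusion_tally <- function(filtered) {
  attr(filtered, "exclusion_tally")
}
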