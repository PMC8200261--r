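# internal helpers: seeding, time arithmetic, small checks

#' Derive a reproducible per-stage seed from a global seed
#'
#' Each pipeline stage draws from its own substream so that, for example,
#' changing only the scoring seed leaves the simulated cohort untouched.
#' The derivation is a small multiplicative hash of the stage name folded
#' into the global seed, kept inside the 32-bit integer range.
#'
#' @param seed integer global seed
#' @param stage character stage label
#' @return integer seed
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(stage) == 1L)
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 1014733
  as.integer((abs(seed) * 2654435 + h * 97 + 13) %% 2147483629)
}

hours_since <- function(timestamp, origin) {
  as.numeric(difftime(timestamp, origin, units = "hours"))
}

hour_of_day <- function(timestamp) {
  as.integer(format(timestamp, "%H", tz = "UTC"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# truncated-normal draw: normal clipped to mean +/- 2 sd, then hard bounds
rnorm_band <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  x <- pmin(pmax(x, mean - 2 * sd), mean + 2 * sd)
  pmin(pmax(x, lo), hi)
}
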