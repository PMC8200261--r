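# Table schemas and delimited I/O. All artifacts are RFC-4180 CSV with a
# commented schema-version header line; timestamps are ISO-8601 UTC.

table_schemas <- function() {
  list(
    encounters = list(
      cols = c("encounter_id", "patient_id", "age", "unit_type",
               "admit_time", "discharge_time", "hospice_flag"),
      time_cols = c("admit_time", "discharge_time")),
    events = list(
      cols = c("encounter_id", "timestamp", "event_type", "vital_kind",
               "value", "oxygen_supplemental", "avpu", "note_concepts"),
      time_cols = "timestamp"),
    outcomes = list(
      cols = c("encounter_id", "event_time", "component"),
      time_cols = character(0)),
    scores = list(
      cols = c("encounter_id", "patient_hour", "system", "score", "category"),
      time_cols = character(0)),
    features = list(
      cols = c("encounter_id", all_feature_columns()),
      time_cols = character(0))
  )
}

iso8601 <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Write / read a schema-validated CSV table
#'
#' Tables carry a commented first line \code{# concernews schema <name> v1}.
#' Reading validates that the column set matches the schema exactly and
#' parses timestamp columns back to POSIXct (UTC).
#'
#' @param x data.frame to write
#' @param path file path
#' @param schema schema name: one of encounters, events, outcomes, scores,
#'   features
#' @return \code{read_table}: the parsed data.frame; \code{write_table}:
#'   the path, invisibly
#' @export
write_table <- function(x, path, schema) {
  sch <- table_schemas()[[schema]]
  if (is.null(sch)) stop("unknown schema: ", schema, call. = FALSE)
  missing <- setdiff(sch$cols, names(x))
  if (length(missing)) {
    stop(sprintf("table lacks schema column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- data.table::as.data.table(x)[, sch$cols, with = FALSE]
  for (tc in sch$time_cols) out[[tc]] <- iso8601(out[[tc]])
  writeLines(sprintf("# concernews schema %s v1", schema), path)
  data.table::fwrite(out, path, append = TRUE, col.names = TRUE,
                     quote = "auto", na = "")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path, schema) {
  sch <- table_schemas()[[schema]]
  if (is.null(sch)) stop("unknown schema: ", schema, call. = FALSE)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  skip <- if (startsWith(first, "#")) 1L else 0L
  dt <- data.table::fread(path, skip = skip, sep = ",", header = TRUE,
                          na.strings = "", colClasses = list(
                            character = intersect(sch$cols,
                                                  c("encounter_id",
                                                    "patient_id"))))
  extra <- setdiff(names(dt), sch$cols)
  missing <- setdiff(sch$cols, names(dt))
  if (length(extra) || length(missing)) {
    stop(sprintf(
      "schema mismatch for '%s'%s%s", schema,
      if (length(missing)) paste0("; missing: ",
                                  paste(missing, collapse = ", ")) else "",
      if (length(extra)) paste0("; unexpected: ",
                                paste(extra, collapse = ", ")) else ""),
      call. = FALSE)
  }
  for (tc in sch$time_cols) {
    dt[[tc]] <- as.POSIXct(dt[[tc]], format = "%Y-%m-%dT%H:%M:%SZ",
                           tz = "UTC")
  }
  data.table::setcolorder(dt, sch$cols)
  data.table::setDF(dt)
  dt
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file with blocks \code{sim}, \code{features},
#' \code{scoring}, \code{evaluation} and a global \code{seed}. Unknown keys
#' anywhere are rejected; every block is validated before any stage runs.
#' A commented template ships in \code{inst/extdata/pipeline-config.yaml}.
#'
#' @param path YAML file path
#' @return object of class \code{pipeline_config}
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config_from_list(raw)
}

#' @rdname read_pipeline_config
#' @param config named list with the same structure as the YAML file
#' @export
pipeline_config_from_list <- function(config) {
  known_top <- c("sim", "features", "scoring", "evaluation", "seed")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  seed <- as.integer(config$seed %||% 1L)

  sim_block <- config$sim %||% list()
  sim_known <- setdiff(names(formals(sim_config)), "seed")
  bad <- setdiff(names(sim_block), sim_known)
  if (length(bad)) {
    stop("unknown sim key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  sim <- do.call(sim_config,
                 c(sim_block, list(seed = derive_seed(seed, "simulate"))))

  feat_defaults <- list(window_hours = 12, common_threshold = 1 / 24)
  feat <- validate_block(config$features, feat_defaults, "features")
  scor_defaults <- list(horizon_hours = 12,
                        cutpoint_quantiles = c(0.80, 0.95), folds = 2,
                        staleness_hours = 12, regularize = "ridge",
                        min_train_events = 5)
  scor <- validate_block(config$scoring, scor_defaults, "scoring")
  eval_defaults <- list(horizons = 1:48, smoothing = 0.5,
                        convention = "exact")
  evl <- validate_block(config$evaluation, eval_defaults, "evaluation")
  if (is.character(evl$horizons)) {
    rng <- as.integer(strsplit(evl$horizons, ":")[[1]])
    evl$horizons <- seq(rng[1], rng[2])
  }

  structure(list(seed = seed, sim = sim, features = feat, scoring = scor,
                 evaluation = evl),
            class = "pipeline_config")
}

validate_block <- function(block, defaults, name) {
  block <- block %||% list()
  bad <- setdiff(names(block), names(defaults))
  if (length(bad)) {
    stop(sprintf("unknown %s key(s): %s", name,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  utils::modifyList(defaults, block)
}
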