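# The behavioral reference scorer: a pooled (discrete-time) logistic model of
# "composite event within the next H hours" over patient-hour feature rows,
# with green/yellow/red categories cut at quantiles of the training-score
# distribution. This is a documented, reproducible stand-in for a production
# behavioral score whose coefficients are proprietary.

#' Fit the behavioral reference scorer
#'
#' Fits a pooled logistic regression of the indicator "first composite event
#' within the next \code{horizon_hours}" on the 55 feature columns, one row
#' per patient-hour. Rows at or after an encounter's event are dropped.
#' The train/test split is always by encounter, never by row. Category
#' cutpoints are quantiles (default 0.80 and 0.95) of the training-score
#' distribution, so roughly 15% of training hours are yellow and 5% red.
#'
#' @param features hourly feature matrix from [build_hourly_features()]
#' @param first_events per-encounter first event table from
#'   [composite_first_event()]
#' @param horizon_hours prediction horizon H (default 12)
#' @param cutpoint_quantiles two increasing probabilities for the
#'   yellow/red cutpoints (default 0.80, 0.95)
#' @param train_encounters encounter ids to train on; if NULL, a fraction
#'   \code{train_frac} of encounters is sampled with \code{seed}
#' @param train_frac fraction of encounters used for training (default 0.5)
#' @param regularize "ridge" (default: weak L2 penalty, which keeps rare
#'   count columns from diverging at desk-scale n) or "none" (plain maximum
#'   likelihood; errors on complete separation, advising ridge)
#' @param lambda ridge penalty on the summed log-likelihood scale (default 1;
#'   the intercept is never penalized)
#' @param seed integer seed for the train/test split
#' @param min_train_events minimum event encounters required in the training
#'   split (default 50)
#' @return object of class \code{concern_scorer}: coefficients, horizon,
#'   cutpoints, train/test encounter ids
#' @export
fit_reference_scorer <- function(features, first_events, horizon_hours = 12,
                                 cutpoint_quantiles = c(0.80, 0.95),
                                 train_encounters = NULL, train_frac = 0.5,
                                 regularize = c("ridge", "none"),
                                 lambda = 1, seed = 1L,
                                 min_train_events = 50L) {
  regularize <- match.arg(regularize)
  if (length(cutpoint_quantiles) != 2 || diff(cutpoint_quantiles) <= 0) {
    stop("cutpoint_quantiles must be two increasing probabilities",
         call. = FALSE)
  }
  enc_ids <- unique(features$encounter_id)
  if (is.null(train_encounters)) {
    set.seed(seed)
    train_encounters <- sample(enc_ids, size = round(train_frac *
                                                       length(enc_ids)))
  }
  test_encounters <- setdiff(enc_ids, train_encounters)

  lab <- label_rows(features, first_events, horizon_hours)
  train <- lab[lab$encounter_id %in% train_encounters, , drop = FALSE]
  n_event_enc <- length(unique(train$encounter_id[train$label]))
  if (n_event_enc < min_train_events) {
    stop(sprintf("training split has %d event encounters (< %d)",
                 n_event_enc, min_train_events), call. = FALSE)
  }

  X <- as.matrix(train[, all_feature_columns()])
  y <- train$label

  if (regularize == "none") {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                     family = stats::binomial()))
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    if (!fit$converged || any(abs(beta[-1]) > 20)) {
      stop(paste("logistic fit did not converge (likely complete",
                 "separation); refit with regularize = 'ridge'"),
           call. = FALSE)
    }
  } else {
    beta <- ridge_logistic(X, y, lambda = lambda)
  }

  train_scores <- as.numeric(stats::plogis(cbind(1, X) %*% beta))
  cutpoints <- stats::quantile(train_scores, cutpoint_quantiles, names = FALSE)
  if (diff(cutpoints) <= 0) {
    stop("degenerate training-score distribution: cutpoints are not strictly",
         " increasing", call. = FALSE)
  }

  structure(list(
    coefficients = beta,
    horizon_hours = horizon_hours,
    cutpoint_quantiles = cutpoint_quantiles,
    cutpoints = cutpoints,
    train_encounters = train_encounters,
    test_encounters = test_encounters,
    regularize = regularize
  ), class = "concern_scorer")
}

# L2-penalized logistic regression by iteratively reweighted least squares;
# columns are standardized internally so the penalty is scale-free, and the
# intercept is unpenalized. Returns coefficients on the original scale.
ridge_logistic <- function(X, y, lambda = 1, max_iter = 50, tol = 1e-9) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  Za <- cbind(1, Z)
  p <- ncol(Za)
  pen <- diag(c(0, rep(lambda, p - 1)))
  obj <- function(b) {
    eta <- drop(Za %*% b)
    # -log-likelihood, numerically stable, plus the L2 penalty
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      lambda / 2 * sum(b[-1]^2)
  }
  beta <- numeric(p)
  beta[1] <- stats::qlogis(max(min(mean(y), 1 - 1e-6), 1e-6))
  f_old <- obj(beta)
  for (it in seq_len(max_iter)) {
    eta <- drop(Za %*% beta)
    prob <- stats::plogis(eta)
    w <- pmax(prob * (1 - prob), 1e-10)
    grad <- drop(crossprod(Za, y - prob)) - drop(pen %*% beta)
    hess <- crossprod(Za * w, Za) + pen
    step <- drop(solve(hess, grad))
    # damped Newton: halve the step until the penalized deviance decreases
    t_step <- 1
    repeat {
      cand <- beta + t_step * step
      f_new <- obj(cand)
      if (f_new <= f_old + 1e-12 || t_step < 1e-6) break
      t_step <- t_step / 2
    }
    moved <- max(abs(t_step * step))
    beta <- cand
    f_old <- f_new
    if (moved < tol) break
  }
  b <- drop(beta)
  out <- c(b[1] - sum(b[-1] * mu / sdv), b[-1] / sdv)
  names(out) <- c("(Intercept)", colnames(X))
  out
}

# label feature rows for the pooled logistic fit. Row t summarises data
# through the end of hour t (time t + 1), so its score is available at
# t + 1 and predicts prospectively: label TRUE when the first event falls
# in (t + 1, t + 1 + H]. Rows whose window could overlap the event itself
# (event_time <= t + 1) are dropped.
label_rows <- function(features, first_events, horizon_hours) {
  fe <- first_events[match(features$encounter_id, first_events$encounter_id), ]
  ev <- fe$event_time
  keep <- is.na(ev) | ev > features$patient_hour + 1
  out <- features[keep, , drop = FALSE]
  ev <- ev[keep]
  out$label <- !is.na(ev) & ev <= out$patient_hour + 1 + horizon_hours
  out
}

#' @export
print.concern_scorer <- function(x, ...) {
  cat("<concern_scorer> pooled logistic, horizon", x$horizon_hours,
      "h;", length(x$train_encounters), "training encounters;",
      sprintf("cutpoints %.4g / %.4g (q %.2f / %.2f)\n", x$cutpoints[1],
              x$cutpoints[2], x$cutpoint_quantiles[1],
              x$cutpoint_quantiles[2]))
  invisible(x)
}

#' @export
predict.concern_scorer <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, all_feature_columns()])
  as.numeric(stats::plogis(cbind(1, X) %*% object$coefficients))
}

#' Hourly CONCERN score series from a fitted scorer
#'
#' A pure function of each feature row: the continuous score is the predicted
#' event probability, and the category (green/yellow/red displayed as
#' low/moderate/high) comes from the scorer's training-quantile cutpoints.
#' Feature row t summarises documentation through the end of hour t, so the
#' resulting score is stamped at patient hour t + 1: every score uses only
#' strictly earlier data, as a prospectively deployed system would.
#'
#' @param scorer a [fit_reference_scorer()] result
#' @param features hourly feature matrix
#' @return data.frame: encounter_id, patient_hour, system = "CONCERN",
#'   score, category
#' @export
concern_score_series <- function(scorer, features) {
  stopifnot(inherits(scorer, "concern_scorer"))
  s <- predict(scorer, features)
  bands <- score_bands("CONCERN", cutpoints = scorer$cutpoints)
  data.frame(
    encounter_id = features$encounter_id,
    patient_hour = features$patient_hour + 1L,
    system = "CONCERN",
    score = s,
    category = as.character(categorize(s, bands)),
    stringsAsFactors = FALSE
  )
}

#' Cross-fitted CONCERN scores for a whole cohort
#'
#' Splits encounters into \code{folds} groups; each group is scored by a
#' scorer (with its own training-quantile cutpoints) fitted on the remaining
#' groups, so no encounter is scored by a model that saw its own outcomes.
#'
#' @inheritParams fit_reference_scorer
#' @param folds number of folds (default 2)
#' @return data.frame as [concern_score_series()], covering all encounters
#' @export
crossfit_concern_scores <- function(features, first_events, folds = 2,
                                    horizon_hours = 12,
                                    cutpoint_quantiles = c(0.80, 0.95),
                                    regularize = "ridge", lambda = 1,
                                    seed = 1L, min_train_events = 50L) {
  enc_ids <- unique(features$encounter_id)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), length(enc_ids)))
  out <- vector("list", folds)
  for (k in seq_len(folds)) {
    train_ids <- enc_ids[fold != k]
    test_ids <- enc_ids[fold == k]
    scorer <- fit_reference_scorer(
      features[features$encounter_id %in% train_ids, , drop = FALSE],
      first_events, horizon_hours = horizon_hours,
      cutpoint_quantiles = cutpoint_quantiles,
      train_encounters = train_ids, regularize = regularize,
      lambda = lambda, seed = seed, min_train_events = min_train_events)
    out[[k]] <- concern_score_series(
      scorer, features[features$encounter_id %in% test_ids, , drop = FALSE])
  }
  res <- do.call(rbind, out)
  res[order(res$encounter_id, res$patient_hour), , drop = FALSE]
}
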