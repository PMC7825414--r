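# Per-sample gradient-boosted tree regression with histogram binning, and
# leave-one-subject-out cross-validation. Wearable signals from one time
# sample predict the target load metric for that same sample; no temporal
# context is used.

#' Gradient-boosted tree configuration
#'
#' Stage-wise ensemble of ~100 histogram-binned regression trees fit to the
#' squared-error residual; leaf-wise growth capped at `max_leaves`.
#'
#' @param n_trees Number of boosting stages (default 100).
#' @param learning_rate Shrinkage per stage.
#' @param max_bins Histogram bins per feature.
#' @param max_leaves Maximum leaves per tree.
#' @param min_samples_leaf Minimum samples per leaf.
#' @param seed Integer seed (the fit is deterministic given config + seed).
#' @return A list of class `ll_gbdt_config`.
#' @export
gbdt_config <- function(n_trees = 100, learning_rate = 0.1, max_bins = 255,
                        max_leaves = 31, min_samples_leaf = 20, seed = 1) {
  if (n_trees < 1) abort("`n_trees` must be >= 1.")
  if (max_bins < 2) abort("`max_bins` must be >= 2.")
  structure(list(n_trees = as.integer(n_trees), learning_rate = learning_rate,
                 max_bins = as.integer(max_bins), max_leaves = as.integer(max_leaves),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 loss = "squared_error", seed = as.integer(seed)),
            class = "ll_gbdt_config")
}

#' Fit a gradient-boosted tree regressor
#'
#' @param features Data frame or matrix of input channels (one row per
#'   sample).
#' @param target Numeric response, same length.
#' @param config An `ll_gbdt_config`.
#' @param channels Channel columns to use (defaults to all registry
#'   channels when `features` is an `ll_features`, else all numeric
#'   non-identifier columns).
#' @return An `ll_gbdt` model (booster + channel schema + config).
#' @export
gbdt_fit <- function(features, target, config = gbdt_config(), channels = NULL) {
  channels <- channels %||% feature_channels(features)
  X <- as.matrix(features[, channels, drop = FALSE])
  if (nrow(X) == 0) abort("empty training set.")
  if (!all(is.finite(target))) abort("non-finite target values.")
  dm <- xgboost::xgb.DMatrix(X, label = target, nthread = 1)
  params <- list(
    objective = "reg:squarederror",
    eta = config$learning_rate,
    tree_method = "hist",
    max_bin = config$max_bins,
    grow_policy = "lossguide",
    max_depth = 0L,
    max_leaves = config$max_leaves,
    min_child_weight = config$min_samples_leaf,
    nthread = 1L,
    seed = config$seed
  )
  booster <- xgboost::xgb.train(params = params, data = dm,
                                nrounds = config$n_trees, verbose = 0)
  structure(list(booster = booster, channels = channels, config = config),
            class = "ll_gbdt")
}

#' Predict per-sample estimates from a fitted model
#'
#' One output per input row; predictions are stateless, so permuting or
#' duplicating rows permutes or duplicates outputs identically.
#'
#' @param model An `ll_gbdt`.
#' @param features Data frame with (at least) the model's channel columns.
#' @return Numeric vector of per-sample estimates.
#' @export
gbdt_predict <- function(model, features) {
  missing <- setdiff(model$channels, names(features))
  if (length(missing) > 0) {
    abort(sprintf("feature schema mismatch; missing channel(s): %s.",
                  paste(head(missing, 5), collapse = ", ")))
  }
  X <- as.matrix(features[, model$channels, drop = FALSE])
  stats::predict(model$booster, xgboost::xgb.DMatrix(X, nthread = 1))
}

#' Leave-one-subject-out cross-validation
#'
#' For each participant: fit the z-score normalizer and the gradient-boosted
#' model on all other participants' samples, then predict the held-out
#' participant. Every sample is predicted exactly once, by a model that
#' never saw that participant.
#'
#' @param dataset A data frame with `participant_id`, `target`, and channel
#'   columns (see [simulate_dataset()]).
#' @param config An `ll_gbdt_config`.
#' @param channels Channel columns (default: registry channels).
#' @return An `ll_loso` object: `$predictions` (tibble with
#'   `participant_id`, `task_id`, `time`, `target`, `prediction`, `fold`),
#'   `$folds` (per-fold model + normalizer), `$channels`, `$config`.
#' @export
loso_cv <- function(dataset, config = gbdt_config(), channels = NULL) {
  channels <- channels %||% feature_channels(dataset)
  ids <- unique(dataset$participant_id)
  if (length(ids) < 2) abort("need at least 2 participants for LOSO CV.")
  counts <- table(dataset$participant_id)
  if (any(counts == 0)) abort("participant with zero samples.")
  folds <- list()
  preds <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    held <- ids[k]
    train <- dataset[dataset$participant_id != held, , drop = FALSE]
    test <- dataset[dataset$participant_id == held, , drop = FALSE]
    norm <- fit_normalizer(train, channels)
    model <- gbdt_fit(apply_normalizer(norm, train), train$target,
                      config = config, channels = channels)
    p <- gbdt_predict(model, apply_normalizer(norm, test))
    preds[[k]] <- tibble::tibble(
      participant_id = test$participant_id,
      task_id = if ("task_id" %in% names(test)) test$task_id else NA_character_,
      time = if ("time" %in% names(test)) test$time else NA_real_,
      target = test$target, prediction = p, fold = k
    )
    folds[[k]] <- list(participant = held, model = model, normalizer = norm)
  }
  structure(list(predictions = dplyr::bind_rows(preds), folds = folds,
                 channels = channels, config = config,
                 cohort = attr(dataset, "cohort")),
            class = "ll_loso")
}

#' @export
print.ll_loso <- function(x, ...) {
  r2 <- r2_by_participant(x$predictions)
  cat(sprintf("LOSO CV: %d folds, %d channels, mean r^2 = %.3f\n",
              length(x$folds), length(x$channels), attr(r2, "mean_r2")))
  invisible(x)
}

#' Tidy per-participant accuracy of a LOSO fit
#'
#' @param x An `ll_loso`.
#' @param ... Unused.
#' @return Tibble with one row per participant: `participant_id`, `r2`,
#'   `rmse` (target units), `n`.
#' @method tidy ll_loso
#' @export
tidy.ll_loso <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$predictions, .data$participant_id),
    r2 = 1 - sum((.data$target - .data$prediction)^2) /
      sum((.data$target - mean(.data$target))^2),
    rmse = sqrt(mean((.data$target - .data$prediction)^2)),
    n = dplyr::n(), .groups = "drop"
  )
}

#' One-row summary of a LOSO fit
#'
#' @param x An `ll_loso`.
#' @param mape_threshold MAPE inclusion threshold in target units.
#' @param ... Unused.
#' @return Tibble with `mean_r2`, `rmse`, `rmse_nm` (when cohort
#'   anthropometry is attached), `mape_pct`, `n_folds`, `n_samples`.
#' @method glance ll_loso
#' @export
glance.ll_loso <- function(x, mape_threshold = 0.05, ...) {
  td <- tidy(x)
  p <- x$predictions
  rmse <- sqrt(mean((p$target - p$prediction)^2))
  rmse_nm <- if (!is.null(x$cohort)) {
    rmse * mean(x$cohort$body_mass) * .GRAVITY * mean(x$cohort$body_height)
  } else NA_real_
  tibble::tibble(
    mean_r2 = mean(td$r2), rmse = rmse, rmse_nm = rmse_nm,
    mape_pct = mape_thresholded(p$prediction, p$target, mape_threshold),
    n_folds = length(x$folds), n_samples = nrow(p)
  )
}
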