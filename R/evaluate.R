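# Accuracy metrics, permutation importance, unit conversions, and paired
# statistics.

#' Coefficient of determination per participant
#'
#' r^2 = 1 - SS_res / SS_tot computed per participant over all of that
#' participant's time samples (not squared Pearson correlation); the mean
#' across participants is attached as the headline value.
#'
#' @param predictions Data frame with `participant_id`, `target`,
#'   `prediction` (e.g. `ll_loso$predictions`).
#' @return Tibble (`participant_id`, `r2`) with attribute `mean_r2`.
#' @export
#' @examples
#' d <- tibble::tibble(participant_id = "p", target = c(1, 2, 3, 4),
#'                     prediction = c(1, 2, 3, 5))
#' r2_by_participant(d)$r2 # 0.8
r2_by_participant <- function(predictions) {
  out <- dplyr::summarise(
    dplyr::group_by(predictions, .data$participant_id),
    r2 = {
      sst <- sum((.data$target - mean(.data$target))^2)
      if (sst == 0) abort("zero-variance target for a participant.")
      1 - sum((.data$target - .data$prediction)^2) / sst
    },
    .groups = "drop"
  )
  attr(out, "mean_r2") <- mean(out$r2)
  out
}

#' Root-mean-square error in BW x BH and newton-metres
#'
#' @param predictions,targets Aligned numeric vectors in BW x BH units.
#' @param cohort Cohort tibble (or single anthropometry); the Nm conversion
#'   multiplies by mean body mass x g x mean body height.
#' @return Tibble with `rmse_bwbh` and `rmse_nm`.
#' @export
rmse_moment <- function(predictions, targets, cohort) {
  if (length(predictions) == 0) abort("empty input.")
  if (length(predictions) != length(targets)) abort("length mismatch.")
  r <- sqrt(mean((predictions - targets)^2))
  k <- mean(cohort$body_mass) * .GRAVITY * mean(cohort$body_height)
  tibble::tibble(rmse_bwbh = r, rmse_nm = r * k)
}

#' Mean absolute percent error above a target threshold
#'
#' MAPE over only the samples whose true value exceeds `threshold`
#' (default 0.05 BW x BH), since percent error is unstable near zero.
#'
#' @param predictions,targets Aligned numeric vectors.
#' @param threshold Inclusion threshold in target units (> 0).
#' @return Percent error (mean of |pred - target| / target x 100).
#' @export
mape_thresholded <- function(predictions, targets, threshold = 0.05) {
  if (threshold <= 0) abort("`threshold` must be > 0.")
  keep <- targets > threshold
  if (!any(keep)) abort("no samples above the MAPE threshold.")
  mean(abs(predictions[keep] - targets[keep]) / targets[keep]) * 100
}

#' Permutation feature importance over held-out folds
#'
#' For each channel: shuffle that channel's values across the held-out
#' samples (within each participant, preserving the fold structure),
#' re-predict, and record the drop in r^2 relative to the unshuffled
#' baseline. Averaged over `repeats` shuffles and all folds.
#'
#' @param fit An `ll_loso`.
#' @param dataset The dataset the fit was produced from.
#' @param repeats Number of shuffle repeats per channel (default 5).
#' @param seed Integer seed.
#' @return An `ll_importance` tibble (`channel`, `delta_r2`, `delta_r2_sd`,
#'   `rank`), sorted by decreasing importance.
#' @export
permutation_importance <- function(fit, dataset, repeats = 5, seed = 1) {
  if (repeats < 1) abort("`repeats` must be >= 1.")
  channels <- fit$channels
  with_seed(seed, {
    drops <- array(NA_real_, dim = c(length(channels), repeats, length(fit$folds)))
    for (k in seq_along(fit$folds)) {
      fold <- fit$folds[[k]]
      test <- dataset[dataset$participant_id == fold$participant, , drop = FALSE]
      if (nrow(test) < 2) abort("single-sample fold input.")
      scaled <- apply_normalizer(fold$normalizer, test)
      base_pred <- gbdt_predict(fold$model, scaled)
      sst <- sum((test$target - mean(test$target))^2)
      base_r2 <- 1 - sum((test$target - base_pred)^2) / sst
      for (ci in seq_along(channels)) {
        ch <- channels[ci]
        for (r in seq_len(repeats)) {
          sh <- scaled
          sh[[ch]] <- sample(sh[[ch]])
          p <- gbdt_predict(fold$model, sh)
          drops[ci, r, k] <- base_r2 - (1 - sum((test$target - p)^2) / sst)
        }
      }
    }
    out <- tibble::tibble(
      channel = channels,
      delta_r2 = apply(drops, 1, mean),
      delta_r2_sd = apply(drops, 1, sd)
    )
    out <- dplyr::arrange(out, dplyr::desc(.data$delta_r2))
    out$rank <- seq_len(nrow(out))
    class(out) <- c("ll_importance", class(out))
    out
  })
}

#' Convert a lumbar extension moment to spine compression force
#'
#' Divides the moment by the lumbar extensor muscle moment arm (default
#' 7 cm).
#'
#' @param moment Moment in N m.
#' @param moment_arm Extensor moment arm in m (> 0).
#' @return Compression force in N.
#' @export
#' @examples
#' moment_to_compression(7) # 100 N
moment_to_compression <- function(moment, moment_arm = 0.07) {
  if (moment_arm <= 0) abort("`moment_arm` must be > 0.")
  moment / moment_arm
}

#' Express a force in multiples of body weight
#'
#' @param force Force in N.
#' @param body_mass Body mass in kg (> 0), e.g. the cohort mean.
#' @return Tibble with the exact value (`bw`) and the one-decimal display
#'   value (`bw_rounded`, rounded half away from zero).
#' @export
#' @examples
#' force_to_bw(3400, 79)$bw_rounded # 4.4
force_to_bw <- function(force, body_mass) {
  if (body_mass <= 0) abort("`body_mass` must be > 0.")
  bw <- force / (body_mass * .GRAVITY)
  tibble::tibble(bw = bw, bw_rounded = round_half_out(bw, 1))
}

#' Two-sided Wilcoxon signed-rank test on paired per-participant accuracies
#'
#' Exact distribution for n <= 25 pairs, normal approximation above. All-
#' zero differences are a degenerate case and raise an error rather than
#' returning a p-value.
#'
#' @param a,b Equal-length paired accuracy vectors (one entry per
#'   participant).
#' @return Two-sided p-value.
#' @export
wilcoxon_paired <- function(a, b) {
  if (length(a) != length(b)) abort("paired vectors must have equal length.")
  d <- a - b
  if (all(d == 0)) abort("all paired differences are zero; test undefined.")
  res <- stats::wilcox.test(a, b, paired = TRUE, exact = length(a) <= 25,
                            correct = FALSE)
  unname(res$p.value)
}
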