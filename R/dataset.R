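# End-to-end dataset assembly: cohort x battery -> per-sample feature rows
# with the normalized lumbar moment target.

target_from_trial <- function(trial, target) {
  anthro <- trial_anthro(trial)
  raw <- switch(target,
    extension = trial$lumbar_ext_nm,
    lateral_bending = trial$lumbar_lat_nm,
    abort("`target` must be 'extension' or 'lateral_bending'."))
  raw / bwbh(anthro)
}

#' Simulate all trials for a cohort and battery
#'
#' @param cohort An `ll_cohort`.
#' @param battery An `ll_battery`.
#' @param rate Sampling rate in Hz.
#' @param seed Master seed; per-trial seeds are spawned from it, so the
#'   same seed reproduces every trial bit-for-bit.
#' @return A list of `ll_trial` objects (one per participant x task).
#' @export
simulate_trials <- function(cohort, battery, rate = 100, seed = 1) {
  n_p <- nrow(cohort); n_t <- nrow(battery)
  seeds <- matrix(spawn_seeds(seed, n_p * n_t), n_p, n_t)
  out <- vector("list", n_p * n_t)
  idx <- 0L
  for (i in seq_len(n_p)) {
    anthro <- cohort_row(cohort, i)
    for (j in seq_len(n_t)) {
      idx <- idx + 1L
      out[[idx]] <- withCallingHandlers(
        simulate_trial(anthro, battery[j, ], rate = rate, seed = seeds[i, j]),
        ll_cop_clipped = function(w) invokeRestart("muffleWarning")
      )
    }
  }
  out
}

#' Build a per-sample dataset from simulated trials
#'
#' Applies (for `"real"` provenance) sensor degradation and the
#' real-emulated feature builder, or the idealized feature builder, then
#' attaches the normalized target and keeps every `stride`-th sample.
#'
#' @param trials List of `ll_trial` (see [simulate_trials()]).
#' @param provenance `"idealized"` or `"real"`.
#' @param noise `ll_noise` used when `provenance = "real"`.
#' @param target `"extension"` or `"lateral_bending"` (BW x BH units).
#' @param stride Keep every `stride`-th sample (default 4; per-sample
#'   estimation is rate-agnostic and the kinematics are 6 Hz band-limited,
#'   so a 25 Hz effective rate loses no information).
#' @param seed Seed for the degradation noise streams.
#' @param cohort Optional cohort to attach (for Nm conversions downstream).
#' @return An `ll_dataset` tibble: `participant_id`, `task_id`, `time`,
#'   `target`, then channel columns; attributes `registry`, `provenance`,
#'   `cohort`.
#' @export
dataset_from_trials <- function(trials, provenance = c("idealized", "real"),
                                noise = noise_config(), target = "extension",
                                stride = 4, seed = 1, cohort = NULL) {
  provenance <- match.arg(provenance)
  seeds <- spawn_seeds(seed + 1L, length(trials))
  rows <- vector("list", length(trials))
  registry <- NULL
  for (i in seq_along(trials)) {
    trial <- trials[[i]]
    if (provenance == "real") {
      trial <- degrade_to_real(trial, noise, seed = seeds[i])
      fm <- build_real_features(trial)
    } else {
      fm <- build_idealized_features(trial)
    }
    if (is.null(registry)) registry <- attr(fm, "registry")
    fm$target <- target_from_trial(trial, target)
    keep <- seq(1, nrow(fm), by = stride)
    rows[[i]] <- fm[keep, c("participant_id", "task_id", "time", "target",
                            registry$channel)]
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "registry") <- registry
  attr(out, "provenance") <- provenance
  attr(out, "cohort") <- cohort
  attr(out, "target_metric") <- target
  class(out) <- c("ll_dataset", class(out))
  out
}

#' Simulate a complete study dataset
#'
#' Convenience wrapper: [simulate_trials()] then [dataset_from_trials()].
#'
#' @inheritParams simulate_trials
#' @inheritParams dataset_from_trials
#' @return An `ll_dataset` tibble.
#' @export
#' @examples
#' \donttest{
#' cohort <- sample_cohort(2, seed = 1)
#' battery <- build_task_battery(masses = c(5, 15), repetitions = 1,
#'                               styles = c("squat", "stoop"))
#' ds <- simulate_dataset(cohort, battery[1:4, ], seed = 1)
#' }
simulate_dataset <- function(cohort, battery, provenance = "idealized",
                             noise = noise_config(), target = "extension",
                             rate = 100, stride = 4, seed = 1) {
  n_p <- nrow(cohort); n_t <- nrow(battery)
  seeds <- matrix(spawn_seeds(seed, n_p * n_t), n_p, n_t)
  noise_seeds <- matrix(spawn_seeds(seed + 1L, n_p * n_t), n_p, n_t)
  rows <- vector("list", n_p * n_t)
  registry <- NULL
  idx <- 0L
  for (i in seq_len(n_p)) {
    anthro <- cohort_row(cohort, i)
    for (j in seq_len(n_t)) {
      idx <- idx + 1L
      trial <- withCallingHandlers(
        simulate_trial(anthro, battery[j, ], rate = rate, seed = seeds[i, j]),
        ll_cop_clipped = function(w) invokeRestart("muffleWarning")
      )
      if (provenance == "real") {
        trial <- degrade_to_real(trial, noise, seed = noise_seeds[i, j])
        fm <- build_real_features(trial)
      } else {
        fm <- build_idealized_features(trial)
      }
      if (is.null(registry)) registry <- attr(fm, "registry")
      fm$target <- target_from_trial(trial, target)
      keep <- seq(1, nrow(fm), by = stride)
      rows[[idx]] <- fm[keep, c("participant_id", "task_id", "time", "target",
                                registry$channel)]
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "registry") <- registry
  attr(out, "provenance") <- provenance
  attr(out, "cohort") <- cohort
  attr(out, "target_metric") <- target
  class(out) <- c("ll_dataset", class(out))
  out
}

#' Per-wearer insole calibration
#'
#' Standardizes the insole channels within each participant's recording
#' session, emulating the per-wearer calibration any deployed insole system
#' performs: normal-force channels are divided by their session mean (a
#' body-weight-scale gain calibration — an insole reads newtons, but only
#' force relative to the wearer's own weight transfers across people), and
#' centre-of-pressure channels are re-centred on their session mean (a
#' stance-origin calibration). Orientation and joint-angle channels are
#' left untouched; they are comparable across wearers as-is. Uses input
#' signals only — no target values and no other participants' data — so it
#' introduces no cross-validation leakage.
#'
#' @param dataset An `ll_dataset` (or `ll_features`) tibble.
#' @return The dataset with calibrated insole channels.
#' @export
calibrate_insoles <- function(dataset) {
  registry <- attr(dataset, "registry")
  if (is.null(registry)) abort("dataset carries no channel registry.")
  force_ch <- registry$channel[registry$kind == "normal_force"]
  cop_ch <- registry$channel[registry$kind %in% c("cop_x", "cop_y")]
  out <- dataset
  for (pid in unique(dataset$participant_id)) {
    idx <- which(dataset$participant_id == pid)
    for (ch in force_ch) {
      mu <- mean(dataset[[ch]][idx])
      if (mu > 1e-9) out[[ch]][idx] <- dataset[[ch]][idx] / mu
    }
    for (ch in cop_ch) {
      out[[ch]][idx] <- dataset[[ch]][idx] - mean(dataset[[ch]][idx])
    }
  }
  out
}

#' Subset an assembled dataset by sensor locations
#'
#' Same rule as [subset_features()], applied to an `ll_dataset` (the
#' `target` column is kept).
#'
#' @param dataset An `ll_dataset`.
#' @param locations Sensor-location subset.
#' @return The reduced `ll_dataset`.
#' @export
subset_dataset <- function(dataset, locations) {
  registry <- attr(dataset, "registry")
  keep <- purrr::map_lgl(registry$requires, ~ all(.x %in% locations))
  if (!any(keep)) abort("no channels available for this location subset.")
  reg2 <- registry[keep, ]
  out <- dataset[, c("participant_id", "task_id", "time", "target", reg2$channel)]
  attr(out, "registry") <- reg2
  attr(out, "provenance") <- attr(dataset, "provenance")
  attr(out, "cohort") <- attr(dataset, "cohort")
  attr(out, "target_metric") <- attr(dataset, "target_metric")
  class(out) <- c("ll_dataset", class(out))
  out
}
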