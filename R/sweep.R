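# Sensor-location subset sweep: every combination of 1 to 5 of the 6
# candidate locations (62 reduced algorithms) plus the full distributed set,
# each run through the complete normalize / LOSO / evaluate pipeline.

#' Enumerate sensor-location subsets
#'
#' All non-empty proper subsets of sizes 1-5 of the six canonical sensor
#' locations (62 reduced combinations) plus the full distributed set, 63 in
#' total, ordered by size then lexicographically.
#'
#' @param locations The six canonical location tokens.
#' @return Named list of character vectors; names join locations with `+`.
#' @export
#' @examples
#' length(enumerate_subsets()) # 63
enumerate_subsets <- function(locations = .LOCATIONS) {
  if (anyDuplicated(locations)) abort("duplicate location tokens.")
  if (!setequal(locations, .LOCATIONS)) {
    abort("`locations` must be the 6 canonical sensor-location tokens.")
  }
  locations <- sort(locations)
  out <- list()
  for (size in 1:6) {
    combos <- utils::combn(locations, size, simplify = FALSE)
    nms <- vapply(combos, paste, "", collapse = "+")
    combos <- combos[order(nms)]
    out <- c(out, combos)
  }
  names(out) <- vapply(out, paste, "", collapse = "+")
  out
}

#' Run the full sensor-subset sweep
#'
#' For each subset: restrict the dataset to the channels that subset of
#' sensor locations supports, run leave-one-subject-out cross-validation,
#' and record accuracy metrics. A failing subset is recorded with a
#' diagnostic and does not abort the sweep. Re-running with the same master
#' seed reproduces every metric exactly.
#'
#' @param dataset An `ll_dataset`.
#' @param subsets List of location subsets (default: all 63).
#' @param config `ll_gbdt_config`; each subset gets an isolated seed spawned
#'   from `config$seed`.
#' @param mape_threshold MAPE inclusion threshold (BW x BH).
#' @return An `ll_sweep` tibble: `subset`, `size`, `n_channels`, `mean_r2`,
#'   `rmse_bwbh`, `rmse_nm`, `mape_pct`, `r2_by_participant` (list column),
#'   `best_per_size`, `note`.
#' @export
run_sweep <- function(dataset, subsets = enumerate_subsets(),
                      config = gbdt_config(), mape_threshold = 0.05) {
  cohort <- attr(dataset, "cohort")
  seeds <- spawn_seeds(config$seed, length(subsets))
  rows <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    locs <- subsets[[i]]
    nm <- names(subsets)[i] %||% paste(locs, collapse = "+")
    rows[[i]] <- tryCatch({
      sub <- subset_dataset(dataset, locs)
      cfg <- config; cfg$seed <- seeds[i]
      fit <- loso_cv(sub, cfg)
      td <- tidy(fit)
      p <- fit$predictions
      rmse <- if (!is.null(cohort)) rmse_moment(p$prediction, p$target, cohort) else
        tibble::tibble(rmse_bwbh = sqrt(mean((p$prediction - p$target)^2)),
                       rmse_nm = NA_real_)
      tibble::tibble(
        subset = nm, size = length(locs),
        n_channels = length(fit$channels),
        mean_r2 = mean(td$r2),
        rmse_bwbh = rmse$rmse_bwbh, rmse_nm = rmse$rmse_nm,
        # MAPE is undefined when no samples exceed the threshold (small
        # targets, e.g. lateral bending); that does not void the row
        mape_pct = tryCatch(
          mape_thresholded(p$prediction, p$target, mape_threshold),
          error = function(e) NA_real_),
        r2_by_participant = list(td),
        note = NA_character_
      )
    }, error = function(e) {
      tibble::tibble(subset = nm, size = length(locs), n_channels = NA_integer_,
                     mean_r2 = NA_real_, rmse_bwbh = NA_real_, rmse_nm = NA_real_,
                     mape_pct = NA_real_, r2_by_participant = list(NULL),
                     note = conditionMessage(e))
    })
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$size, .data$subset)
  # best-per-size flag; ties broken by fewer channels, then subset name
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$size),
    best_per_size = !is.na(.data$mean_r2) &
      dplyr::row_number(dplyr::desc(.data$mean_r2) * 1e9 +
                          dplyr::coalesce(.data$n_channels, 0L)) == 1L
  )
  out <- dplyr::ungroup(out)
  class(out) <- c("ll_sweep", class(out))
  out
}

#' Best accuracy per subset size
#'
#' @param sweep An `ll_sweep`.
#' @return Tibble with one row per subset size (the flagged best rows).
#' @export
best_per_size <- function(sweep) {
  dplyr::arrange(dplyr::filter(sweep, .data$best_per_size), .data$size)
}
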