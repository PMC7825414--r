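# Plain-text exchange formats: one CSV per trial (wide per-sample schema)
# with a JSON sidecar carrying trial metadata; cohort and battery as CSV
# manifests.

#' Write / read a trial as a columnar CSV with a JSON metadata sidecar
#'
#' The CSV holds the wide per-sample schema (one column per documented
#' channel); `<path>.meta.json` records participant, task, rate,
#' anthropometry and the degraded flag.
#'
#' @param trial An `ll_trial`.
#' @param path Output CSV path.
#' @return `write_trial` returns `path` invisibly; `read_trial` returns the
#'   `ll_trial`.
#' @export
write_trial <- function(trial, path) {
  readr::write_csv(tibble::as_tibble(unclass(trial)), path)
  anthro <- trial_anthro(trial)
  meta <- list(
    participant_id = attr(trial, "participant_id"),
    task_id = attr(trial, "task_id"),
    rate = attr(trial, "rate"),
    degraded = isTRUE(attr(trial, "degraded")),
    anthro = as.list(tibble::as_tibble(anthro)[1, ]),
    segment_params = segment_params_of(anthro)
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  anthro <- anthropometry(
    meta$anthro$participant_id, meta$anthro$body_mass, meta$anthro$body_height,
    sex = meta$anthro$sex %||% NA_character_,
    bend_style = meta$anthro$bend_style %||% 0,
    segment_params = tibble::as_tibble(meta$segment_params)
  )
  attr(df, "participant_id") <- meta$participant_id
  attr(df, "task_id") <- meta$task_id
  attr(df, "rate") <- meta$rate
  attr(df, "anthro") <- anthro
  attr(df, "degraded") <- isTRUE(meta$degraded)
  class(df) <- c("ll_trial", class(df))
  df
}

#' Write cohort / battery manifests
#'
#' @param x An `ll_cohort` or `ll_battery`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  readr::write_csv(tibble::as_tibble(unclass(x)), path)
  invisible(path)
}
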