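# Task battery: the cross-product of box masses, shelf origin/destination
# pairs, and movement styles, repeated and shuffled deterministically. The
# default factorization (5 masses x 5 shelf pairs x 4 styles x 4 repetitions)
# yields the ~400 pick-and-place tasks per participant that the emulated
# protocol calls for; a single repetition gives a 100-task battery.

.SHELF_HEIGHTS <- c(low = 0.30, mid = 1.00, high = 1.50) # m above the floor

.DEFAULT_SHELF_PAIRS <- list(
  c("low", "mid"), c("mid", "low"), c("low", "high"),
  c("high", "low"), c("mid", "high")
)

.STYLES <- c("squat", "stoop", "lateral", "diagonal")

#' Construct a single task specification
#'
#' @param task_id Token.
#' @param box_mass Object mass in kg, 0 to 23 (0 = no-load bend).
#' @param origin_shelf,destination_shelf Shelf levels (`"low"`, `"mid"`,
#'   `"high"`).
#' @param origin_offset,destination_offset Lateral shelf offsets in m
#'   (positive to the participant's right).
#' @param style Movement style: `"squat"`, `"stoop"`, `"lateral"`, or
#'   `"diagonal"`.
#' @param duration Task duration in s.
#' @param pick_time,place_time Load pick-up / set-down times in s, with
#'   `0 < pick_time < place_time < duration`.
#' @return A one-row tibble of class `ll_task`.
#' @export
task_spec <- function(task_id, box_mass, origin_shelf, destination_shelf,
                      origin_offset = 0, destination_offset = 0,
                      style = "squat", duration = 4.5,
                      pick_time = 0.25 * duration, place_time = 0.75 * duration) {
  if (box_mass < 0 || box_mass > 23) abort("`box_mass` must be in [0, 23] kg.")
  if (!style %in% .STYLES) abort("unknown movement style.")
  if (!(0 < pick_time && pick_time < place_time && place_time < duration)) {
    abort("require 0 < pick_time < place_time < duration.")
  }
  if (!origin_shelf %in% names(.SHELF_HEIGHTS) ||
      !destination_shelf %in% names(.SHELF_HEIGHTS)) {
    abort("shelves must be one of 'low', 'mid', 'high'.")
  }
  out <- tibble::tibble(
    task_id = as.character(task_id), box_mass = box_mass,
    origin_shelf = origin_shelf, destination_shelf = destination_shelf,
    origin_offset = origin_offset, destination_offset = destination_offset,
    style = style, duration = duration,
    pick_time = pick_time, place_time = place_time
  )
  class(out) <- c("ll_task", class(out))
  out
}

#' Build the pick-and-place task battery
#'
#' Generates the full cross product of the supplied factors, repeated
#' `repetitions` times, and shuffles the order deterministically under
#' `seed`. Lateral and diagonal styles receive lateral shelf offsets;
#' repetitions receive small seeded duration jitter so no two trials are
#' identical in timing.
#'
#' @param masses Box masses in kg (0 allowed for no-load bends).
#' @param shelf_pairs List of length-2 character vectors
#'   `c(origin, destination)`.
#' @param styles Subset of `c("squat", "stoop", "lateral", "diagonal")`.
#' @param repetitions Number of repetitions of the full cross product.
#' @param duration Nominal task duration in s (jittered +/- 10% per task).
#' @param seed Integer seed for the shuffle and jitter.
#' @return A tibble of class `ll_battery` with one row per task;
#'   `nrow = length(masses) * length(shelf_pairs) * length(styles) *
#'   repetitions`.
#' @export
#' @examples
#' nrow(build_task_battery(repetitions = 1)) # 100 tasks
#' nrow(build_task_battery())                # 400 tasks
build_task_battery <- function(masses = c(0, 5, 10, 15, 23),
                               shelf_pairs = .DEFAULT_SHELF_PAIRS,
                               styles = .STYLES,
                               repetitions = 4,
                               duration = 4.5,
                               seed = 202101) {
  if (length(masses) == 0 || length(shelf_pairs) == 0 || length(styles) == 0 ||
      repetitions < 1) {
    abort("battery factors must be non-empty and repetitions >= 1.")
  }
  grid <- tidyr::expand_grid(
    rep = seq_len(repetitions),
    mass = masses,
    pair = seq_along(shelf_pairs),
    style = styles
  )
  with_seed(seed, {
    grid <- grid[sample.int(nrow(grid)), ]
    dur <- duration * runif(nrow(grid), 0.9, 1.1)
    lat <- ifelse(grid$style %in% c("lateral", "diagonal"),
                  sample(c(-0.35, 0.35), nrow(grid), replace = TRUE), 0)
    out <- purrr::pmap_dfr(
      list(seq_len(nrow(grid)), grid$mass, grid$pair, grid$style, dur, lat),
      function(i, m, p, s, d, l) {
        pr <- shelf_pairs[[p]]
        task_spec(
          task_id = sprintf("t%04d", i), box_mass = m,
          origin_shelf = pr[1], destination_shelf = pr[2],
          origin_offset = if (s == "lateral") l else 0,
          destination_offset = if (s %in% c("lateral", "diagonal")) l else 0,
          style = s, duration = d
        )
      }
    )
    class(out) <- c("ll_battery", class(out))
    out
  })
}
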