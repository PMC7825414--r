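# Anthropometry and segment inertial parameters.
#
# The body model has 8 rigid segments (2 feet, 2 shanks, 2 thighs, pelvis,
# trunk with head and arms lumped in) plus the handheld object as a point mass
# at the hand point. Segment masses, lengths, centre-of-mass positions and
# radii of gyration are Winter-style dimensionless fractions of body mass and
# height, stored as a plain table so they can be overridden in configuration.

#' Default segment inertial parameter table
#'
#' Dimensionless segment parameters in the style of the classical
#' anthropometric proportion tables: per-segment mass fraction of body mass,
#' length fraction of body height, centre-of-mass position as a fraction of
#' segment length from the proximal end, and transverse radius of gyration as
#' a fraction of segment length. Bilateral segments appear once per side so
#' the mass fractions over all modeled segments sum to exactly 1; the trunk
#' row absorbs head and arms.
#'
#' @return A tibble with columns `segment`, `mass_frac`, `length_frac`,
#'   `com_frac`, `rog_frac`.
#' @export
#' @examples
#' sum(default_segment_params()$mass_frac) # exactly 1
default_segment_params <- function() {
  tibble::tribble(
    ~segment,  ~mass_frac, ~length_frac, ~com_frac, ~rog_frac,
    "foot_r",   0.0145,     0.152,        0.50,      0.475,
    "foot_l",   0.0145,     0.152,        0.50,      0.475,
    "shank_r",  0.0465,     0.246,        0.433,     0.302,
    "shank_l",  0.0465,     0.246,        0.433,     0.302,
    "thigh_r",  0.1000,     0.245,        0.433,     0.323,
    "thigh_l",  0.1000,     0.245,        0.433,     0.323,
    "pelvis",   0.1420,     0.090,        0.500,     0.400,
    "trunk",    0.5360,     0.288,        0.450,     0.496
  )
}

# Fixed body-geometry fractions of height (declared model constants).
.GEOM <- list(
  ankle_height = 0.039,
  hip_halfwidth = 0.090,   # lateral offset of each hip/foot from the midline
  foot_back = 0.25,        # fraction of foot length behind the ankle
  arm_length = 0.350       # shoulder-to-hand reach with slight elbow bend
)

#' Construct an anthropometry record
#'
#' @param participant_id Token identifying the participant.
#' @param body_mass Body mass in kg (> 0).
#' @param body_height Body height (stature) in m (> 0).
#' @param sex Optional metadata token.
#' @param bend_style Dimensionless participant-level preference added to the
#'   stoop-vs-squat mix when solving postures (0 = neutral).
#' @param segment_params Segment parameter table; defaults to
#'   [default_segment_params()].
#' @return A one-row tibble of class `ll_anthro`.
#' @export
#' @examples
#' a <- anthropometry("p01", body_mass = 79, body_height = 1.8)
#' body_weight(a) # 79 * 9.81 N
anthropometry <- function(participant_id, body_mass, body_height,
                          sex = NA_character_, bend_style = 0,
                          segment_params = default_segment_params()) {
  stop_if_not_scalar_number(body_mass, "body_mass", positive = TRUE)
  stop_if_not_scalar_number(body_height, "body_height", positive = TRUE)
  if (abs(sum(segment_params$mass_frac) - 1) > 1e-9) {
    abort("segment mass fractions must sum to 1.")
  }
  out <- tibble::tibble(
    participant_id = as.character(participant_id),
    body_mass = body_mass, body_height = body_height,
    sex = sex, bend_style = bend_style
  )
  attr(out, "segment_params") <- segment_params
  class(out) <- c("ll_anthro", class(out))
  out
}

#' Body weight in newtons
#' @param anthro An `ll_anthro` record.
#' @return Body weight `body_mass * g` in N.
#' @export
body_weight <- function(anthro) anthro$body_mass * .GRAVITY

#' Moment normalization constant body weight x body height (N m)
#' @inheritParams body_weight
#' @return `body_mass * g * body_height`.
#' @export
bwbh <- function(anthro) anthro$body_mass * .GRAVITY * anthro$body_height

segment_params_of <- function(anthro) {
  attr(anthro, "segment_params") %||% default_segment_params()
}

# Resolved per-segment absolute parameters for one participant.
segment_table <- function(anthro) {
  sp <- segment_params_of(anthro)
  dplyr::mutate(sp,
    mass = .data$mass_frac * anthro$body_mass,
    length = .data$length_frac * anthro$body_height
  )
}

#' Sample a synthetic participant cohort
#'
#' Heights are drawn from a truncated normal; masses are drawn conditionally
#' on height through body-mass index (BMI truncated to a physiological
#' range), so that height and mass are positively correlated as they are in
#' any real cohort, while reproducing the requested marginal moments —
#' defaults follow the emulated study population (height 1.8 +/- 0.1 m,
#' mass 79 +/- 14 kg, 10 participants). A per-participant `bend_style`
#' preference is also drawn so that movement strategies differ between
#' individuals, which is what makes leave-one-subject-out validation
#' meaningful.
#'
#' @param n Number of participants (>= 1).
#' @param height_mean,height_sd Height moments in m.
#' @param mass_mean,mass_sd Target mass moments in kg (achieved through the
#'   BMI draw).
#' @param height_bounds,mass_bounds Truncation bounds (length-2).
#' @param bend_style_sd Spread of the participant-level posture preference.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A tibble of class `ll_cohort`, one row per participant, with a
#'   `segment_params` attribute shared by all rows.
#' @export
#' @examples
#' cohort <- sample_cohort(10, seed = 1)
#' mean(cohort$body_mass)
sample_cohort <- function(n, height_mean = 1.8, height_sd = 0.1,
                          mass_mean = 79, mass_sd = 14,
                          height_bounds = c(1.5, 2.1),
                          mass_bounds = c(45, 130),
                          bend_style_sd = 0.12,
                          seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) abort("`n` must be >= 1.")
  if (height_sd < 0 || mass_sd < 0) abort("standard deviations must be >= 0.")
  if (height_bounds[1] > height_bounds[2] || mass_bounds[1] > mass_bounds[2]) {
    abort("truncation bounds are inverted.")
  }
  n <- as.integer(n)
  with_seed(seed, {
    heights <- rtruncnorm(n, height_mean, height_sd, height_bounds[1], height_bounds[2])
    # mass = BMI x height^2; BMI moments chosen so the mass marginal matches
    bmi_mean <- mass_mean / (height_mean^2 + height_sd^2)
    var_from_h <- (2 * bmi_mean * height_mean * height_sd)^2
    bmi_sd <- sqrt(max(mass_sd^2 - var_from_h, 0)) / height_mean^2
    bmi <- rtruncnorm(n, bmi_mean, bmi_sd, 16, 36)
    masses <- pmin(mass_bounds[2], pmax(mass_bounds[1], bmi * heights^2))
    styles <- rnorm(n, 0, bend_style_sd)
    sexes <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.3, 0.7))
    out <- tibble::tibble(
      participant_id = sprintf("p%02d", seq_len(n)),
      body_mass = masses, body_height = heights,
      sex = sexes, bend_style = styles
    )
    attr(out, "segment_params") <- default_segment_params()
    class(out) <- c("ll_cohort", class(out))
    out
  })
}

#' Extract one participant's anthropometry record from a cohort
#'
#' @param cohort An `ll_cohort`.
#' @param i Row index.
#' @return An `ll_anthro` one-row tibble.
#' @export
cohort_row <- function(cohort, i) {
  anthropometry(cohort$participant_id[i], cohort$body_mass[i],
                cohort$body_height[i], cohort$sex[i], cohort$bend_style[i],
                segment_params = attr(cohort, "segment_params") %||% default_segment_params())
}
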