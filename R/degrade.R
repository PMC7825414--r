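# Real-wearable-sensor emulation: selective degradation of the channels a
# physical IMU or pressure insole would report. Ground truth, joint centers
# and CoM kinematics (lab quantities) are untouched.

#' Construct a sensor noise configuration
#'
#' Defaults emulate the qualitative picture that insole force variability
#' dominates the degradation while IMU orientation tracking is compara-
#' tively clean: a per-trial multiplicative gain error and additive white
#' noise on insole forces, white noise on the centre of pressure, and a
#' per-trial orientation bias plus white angular noise on each IMU. A
#' zero-valued configuration degrades nothing.
#'
#' @param insole_gain_sd Per-trial multiplicative gain sd (dimensionless).
#' @param insole_additive_sd Per-sample additive force noise sd (N).
#' @param insole_saturation Force saturation ceiling (N, `Inf` = none).
#' @param cop_sd Centre-of-pressure noise sd (m).
#' @param imu_angle_bias_sd Per-trial orientation bias sd (degrees).
#' @param imu_angle_white_sd Per-sample orientation white noise sd (degrees).
#' @return A list of class `ll_noise`.
#' @export
noise_config <- function(insole_gain_sd = 0.08, insole_additive_sd = 10,
                         insole_saturation = Inf, cop_sd = 0.005,
                         imu_angle_bias_sd = 1, imu_angle_white_sd = 0.5) {
  vals <- c(insole_gain_sd, insole_additive_sd, cop_sd,
            imu_angle_bias_sd, imu_angle_white_sd)
  if (any(vals < 0)) abort("noise standard deviations must be >= 0.")
  if (insole_saturation <= 0) abort("`insole_saturation` must be > 0.")
  structure(list(
    insole_gain_sd = insole_gain_sd, insole_additive_sd = insole_additive_sd,
    insole_saturation = insole_saturation, cop_sd = cop_sd,
    imu_angle_bias_sd = imu_angle_bias_sd, imu_angle_white_sd = imu_angle_white_sd
  ), class = "ll_noise")
}

#' Zero-noise configuration (identity degradation)
#' @return An `ll_noise` whose application leaves a trial bit-identical.
#' @export
noise_config_zero <- function() {
  noise_config(0, 0, Inf, 0, 0, 0)
}

is_zero_noise <- function(noise) {
  noise$insole_gain_sd == 0 && noise$insole_additive_sd == 0 &&
    !is.finite(noise$insole_saturation) && noise$cop_sd == 0 &&
    noise$imu_angle_bias_sd == 0 && noise$imu_angle_white_sd == 0
}

# Perturb a quaternion channel block: per-trial bias rotation about a random
# axis plus per-sample white rotations.
perturb_quat <- function(q, bias_deg_sd, white_deg_sd) {
  n <- nrow(q)
  rand_axis <- function(m) {
    v <- matrix(rnorm(3 * m), m, 3)
    v / sqrt(rowSums(v^2))
  }
  bias_ang <- rnorm(1, 0, bias_deg_sd) * pi / 180
  qb <- quat_from_axis_angle(rand_axis(1), bias_ang)
  qb <- matrix(qb, n, 4, byrow = TRUE)
  qw <- quat_from_axis_angle(rand_axis(n), rnorm(n, 0, white_deg_sd) * pi / 180)
  quat_mult(quat_mult(qb, qw), q)
}

#' Degrade an ideal trial into real-wearable-sensor form
#'
#' Applies the noise configuration to the insole-facing channels (per-foot
#' GRF and CoP) and the IMU-facing orientation channels (segment
#' quaternions). Angular-velocity, linear-acceleration, joint-center and
#' ground-truth columns are untouched. A zero configuration returns the
#' input unchanged. Deterministic given `seed`.
#'
#' @param trial A noise-free `ll_trial`.
#' @param noise An `ll_noise` configuration (see [noise_config()]).
#' @param seed Integer seed.
#' @return The degraded `ll_trial` (attribute `degraded = TRUE` when any
#'   noise is configured).
#' @export
degrade_to_real <- function(trial, noise = noise_config(), seed = NULL) {
  if (isTRUE(attr(trial, "degraded"))) abort("trial is already degraded.")
  if (is_zero_noise(noise)) return(trial)
  with_seed(seed, {
    out <- trial
    n <- nrow(trial)
    for (side in c("r", "l")) {
      gain <- 1 + rnorm(1, 0, noise$insole_gain_sd)
      for (ax in c("x", "y", "z")) {
        cn <- paste0("grf_", side, "_", ax)
        v <- trial[[cn]] * gain + rnorm(n, 0, noise$insole_additive_sd)
        out[[cn]] <- pmin(v, noise$insole_saturation)
      }
      for (ax in c("x", "z")) {
        cn <- paste0("cop_", side, "_", ax)
        out[[cn]] <- trial[[cn]] + rnorm(n, 0, noise$cop_sd)
      }
    }
    if (noise$imu_angle_bias_sd > 0 || noise$imu_angle_white_sd > 0) {
      for (s in .SEGMENTS) {
        q <- perturb_quat(trial_quat(trial, s), noise$imu_angle_bias_sd,
                          noise$imu_angle_white_sd)
        out[[paste0(s, "_qw")]] <- q[, 1]; out[[paste0(s, "_qx")]] <- q[, 2]
        out[[paste0(s, "_qy")]] <- q[, 3]; out[[paste0(s, "_qz")]] <- q[, 4]
      }
    }
    attr(out, "degraded") <- TRUE
    attr(out, "noise") <- noise
    out
  })
}
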