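# Wearable channel sets.
#
# Idealized set (51 channels): 8 segments x 3 Euler angles (24), 7 joints x
# 3 angles (21), 2 insole normal forces, 4 insole CoP components.
# Real-emulated set (179 channels): 11 segments (pelvis, L5, L3, T12, T8,
# R/L thigh, shank, foot) x {3 Euler + 4 quaternion + 3 angular velocity +
# 3 linear acceleration} plus 10 joints x 3 angles and the same 6 insole
# channels. The trunk-mounted IMU is exported as the T8 segment; L5, L3 and
# T12 are emulated by spherical interpolation between the pelvis and trunk
# orientations (model-based spine export), so they require both the pelvis
# and trunk sensors when subsetting.
#
# Subsetting rule: a channel is available for a sensor-location subset iff
# every location it requires is present; a joint angle requires both
# adjacent segments' IMUs.

.LOCATIONS <- c("trunk", "pelvis", "thigh", "shank", "foot", "insole")

.SPINE_FRACS <- c(l5 = 0.2, l3 = 0.45, t12 = 0.7)

.registry_cache <- new.env(parent = emptyenv())

reg_row <- function(channel, location, kind, units, requires) {
  tibble::tibble(channel = channel, location = location, kind = kind,
                 units = units, requires = list(requires))
}

seg_location <- function(seg) {
  switch(seg,
    foot_r = , foot_l = "foot",
    shank_r = , shank_l = "shank",
    thigh_r = , thigh_l = "thigh",
    pelvis = "pelvis",
    t8 = , trunk = "trunk",
    l5 = , l3 = , t12 = "spine",
    abort("unknown segment."))
}

seg_requires <- function(seg) {
  loc <- seg_location(seg)
  if (loc == "spine") c("pelvis", "trunk") else loc
}

.JOINTS_IDEAL <- list(
  ankle_r = c("foot_r", "shank_r"), ankle_l = c("foot_l", "shank_l"),
  knee_r = c("shank_r", "thigh_r"), knee_l = c("shank_l", "thigh_l"),
  hip_r = c("thigh_r", "pelvis"), hip_l = c("thigh_l", "pelvis"),
  lumbar = c("pelvis", "trunk")
)

.JOINTS_REAL <- list(
  ankle_r = c("foot_r", "shank_r"), ankle_l = c("foot_l", "shank_l"),
  knee_r = c("shank_r", "thigh_r"), knee_l = c("shank_l", "thigh_l"),
  hip_r = c("thigh_r", "pelvis"), hip_l = c("thigh_l", "pelvis"),
  l5s1 = c("pelvis", "l5"), l4l3 = c("l5", "l3"),
  l1t12 = c("l3", "t12"), t9t8 = c("t12", "t8")
)

joint_requires <- function(segs) unique(unlist(lapply(segs, seg_requires)))

insole_registry <- function() {
  dplyr::bind_rows(
    reg_row("ins_force_r", "insole", "normal_force", "N", "insole"),
    reg_row("ins_force_l", "insole", "normal_force", "N", "insole"),
    reg_row("ins_cop_r_x", "insole", "cop_x", "m", "insole"),
    reg_row("ins_cop_r_y", "insole", "cop_y", "m", "insole"),
    reg_row("ins_cop_l_x", "insole", "cop_x", "m", "insole"),
    reg_row("ins_cop_l_y", "insole", "cop_y", "m", "insole")
  )
}

#' Channel registry for a feature provenance
#'
#' Metadata for every channel in the idealized (51-channel) or real-emulated
#' (179-channel) wearable feature set: name, sensor location, signal kind,
#' units, and the set of sensor locations the channel requires when
#' subsetting.
#'
#' @param provenance `"idealized"` or `"real"`.
#' @return A tibble with columns `channel`, `location`, `kind`, `units`,
#'   `requires` (list column).
#' @export
#' @examples
#' nrow(channel_registry("idealized")) # 51
#' nrow(channel_registry("real"))      # 179
channel_registry <- function(provenance = c("idealized", "real")) {
  provenance <- match.arg(provenance)
  if (!is.null(.registry_cache[[provenance]])) {
    return(.registry_cache[[provenance]])
  }
  ax3 <- c("z", "x", "y") # Euler sequence order: sagittal first
  rows <- list()
  if (provenance == "idealized") {
    for (s in .SEGMENTS) {
      for (ax in ax3) {
        rows[[length(rows) + 1]] <- reg_row(
          paste0("eul_", s, "_", ax), seg_location(s), "euler_angle", "rad",
          seg_requires(s))
      }
    }
    for (j in names(.JOINTS_IDEAL)) {
      for (ax in ax3) {
        rows[[length(rows) + 1]] <- reg_row(
          paste0("jang_", j, "_", ax), "joint", "joint_angle", "rad",
          joint_requires(.JOINTS_IDEAL[[j]]))
      }
    }
  } else {
    segs <- c("pelvis", "l5", "l3", "t12", "t8",
              "thigh_r", "thigh_l", "shank_r", "shank_l", "foot_r", "foot_l")
    for (s in segs) {
      for (ax in ax3) {
        rows[[length(rows) + 1]] <- reg_row(
          paste0("eul_", s, "_", ax), seg_location(s), "euler_angle", "rad",
          seg_requires(s))
      }
    }
    for (s in segs) {
      for (ax in c("w", "x", "y", "z")) {
        rows[[length(rows) + 1]] <- reg_row(
          paste0("quat_", s, "_", ax), seg_location(s), "quaternion", "1",
          seg_requires(s))
      }
    }
    for (s in segs) {
      for (ax in c("x", "y", "z")) {
        rows[[length(rows) + 1]] <- reg_row(
          paste0("avel_", s, "_", ax), seg_location(s), "angular_velocity",
          "rad/s", seg_requires(s))
      }
    }
    for (s in segs) {
      for (ax in c("x", "y", "z")) {
        rows[[length(rows) + 1]] <- reg_row(
          paste0("lacc_", s, "_", ax), seg_location(s), "linear_acceleration",
          "m/s^2", seg_requires(s))
      }
    }
    for (j in names(.JOINTS_REAL)) {
      for (ax in ax3) {
        rows[[length(rows) + 1]] <- reg_row(
          paste0("jang_", j, "_", ax), "joint", "joint_angle", "rad",
          joint_requires(.JOINTS_REAL[[j]]))
      }
    }
  }
  out <- dplyr::bind_rows(c(rows, list(insole_registry())))
  .registry_cache[[provenance]] <- out
  out
}

euler_cols <- function(q) euler_zxy_from_rotmat(rotmat_from_quat(q))

rel_euler <- function(q_prox, q_dist) {
  euler_cols(quat_mult(quat_conj(q_prox), q_dist))
}

insole_channels <- function(trial, quat_r, quat_l) {
  anthro <- trial_anthro(trial)
  l_f <- 0.152 * anthro$body_height
  ah <- .GEOM$ankle_height * anthro$body_height
  ins <- list()
  for (side in c("r", "l")) {
    q <- if (side == "r") quat_r else quat_l
    R <- rotmat_from_quat(q)
    heel <- cols3(trial, paste0("jc_ankle_", side)) +
      rotmat_apply(R, c(-.GEOM$foot_back * l_f, -ah, 0))
    pr <- idealize_insole(cols3(trial, paste0("grf_", side)),
                          cols3(trial, paste0("cop_", side)), q, heel)
    ins[[paste0("ins_force_", side)]] <- pr$normal_force
    ins[[paste0("ins_cop_", side, "_x")]] <- pr$cop_x
    ins[[paste0("ins_cop_", side, "_y")]] <- pr$cop_y
  }
  ins
}

features_tibble <- function(trial, cols, registry, provenance) {
  vals <- cols[registry$channel]
  if (any(vapply(vals, anyNA, logical(1)))) {
    abort("missing values after feature assembly.")
  }
  out <- tibble::new_tibble(c(
    list(participant_id = rep(attr(trial, "participant_id"), nrow(trial)),
         task_id = rep(attr(trial, "task_id"), nrow(trial)),
         time = trial$time),
    vals
  ), nrow = nrow(trial))
  attr(out, "registry") <- registry
  attr(out, "provenance") <- provenance
  attr(out, "rate") <- attr(trial, "rate")
  class(out) <- c("ll_features", class(out))
  out
}

#' Build the idealized wearable feature set for one trial
#'
#' 51 channels: per-segment Euler angles (Z-X-Y, sagittal first), joint
#' angles (distal segment relative to proximal), and the idealized insole
#' projection (normal force and planar CoP per foot).
#'
#' @param trial A noise-free `ll_trial`.
#' @return An `ll_features` tibble (`participant_id`, `task_id`, `time`,
#'   then 51 channel columns) with a `registry` attribute.
#' @export
build_idealized_features <- function(trial) {
  registry <- channel_registry("idealized")
  quats <- lapply(setNames(.SEGMENTS, .SEGMENTS), function(s) trial_quat(trial, s))
  cols <- list()
  for (s in .SEGMENTS) {
    e <- euler_cols(quats[[s]])
    cols[[paste0("eul_", s, "_z")]] <- e[, 1]
    cols[[paste0("eul_", s, "_x")]] <- e[, 2]
    cols[[paste0("eul_", s, "_y")]] <- e[, 3]
  }
  for (j in names(.JOINTS_IDEAL)) {
    pr <- .JOINTS_IDEAL[[j]]
    e <- rel_euler(quats[[pr[2]]], quats[[pr[1]]])
    cols[[paste0("jang_", j, "_z")]] <- e[, 1]
    cols[[paste0("jang_", j, "_x")]] <- e[, 2]
    cols[[paste0("jang_", j, "_y")]] <- e[, 3]
  }
  cols <- c(cols, insole_channels(trial, quats$foot_r, quats$foot_l))
  features_tibble(trial, cols, registry, "idealized")
}

#' Build the real-emulated wearable feature set for one trial
#'
#' 179 channels over 11 segments and 10 joints plus insoles. For degraded
#' trials the orientation channels are low-pass filtered at 6 Hz and the
#' insole force/CoP channels at 10 Hz (3rd-order zero-lag Butterworth)
#' before feature extraction, mirroring lab practice when ingesting noisy
#' signals; analytic (noise-free) trials bypass the filters.
#'
#' @param trial An `ll_trial`, normally after [degrade_to_real()].
#' @return An `ll_features` tibble with 179 channel columns.
#' @export
build_real_features <- function(trial) {
  registry <- channel_registry("real")
  rate <- attr(trial, "rate")
  degraded <- isTRUE(attr(trial, "degraded"))

  smooth_quat <- function(q) {
    if (!degraded) return(q)
    e <- euler_cols(q)
    e <- apply(e, 2, lowpass_zero_lag, cutoff = 6, rate = rate)
    R <- rotmat_mult(rotmat_z(e[, 1]), rotmat_mult(rotmat_x(e[, 2]), rotmat_y(e[, 3])))
    quat_from_rotmat(R)
  }
  base <- c("pelvis", "trunk", "thigh_r", "thigh_l", "shank_r", "shank_l",
            "foot_r", "foot_l")
  quats <- lapply(setNames(base, base), function(s) smooth_quat(trial_quat(trial, s)))
  # model-based spine export: slerp between pelvis and trunk; T8 carries the
  # trunk IMU itself
  quats$t8 <- quats$trunk
  for (s in names(.SPINE_FRACS)) {
    quats[[s]] <- quat_slerp(quats$pelvis, quats$trunk, .SPINE_FRACS[[s]])
  }
  avel <- function(s) {
    if (s %in% .SEGMENTS) return(cols3(trial, paste0(s, "_w")))
    if (s == "t8") return(cols3(trial, "trunk_w"))
    f <- .SPINE_FRACS[[s]]
    (1 - f) * cols3(trial, "pelvis_w") + f * cols3(trial, "trunk_w")
  }
  lacc <- function(s) {
    if (s %in% .SEGMENTS) return(cols3(trial, paste0(s, "_a")))
    if (s == "t8") return(cols3(trial, "trunk_a"))
    f <- .SPINE_FRACS[[s]]
    (1 - f) * cols3(trial, "pelvis_a") + f * cols3(trial, "trunk_a")
  }
  segs <- c("pelvis", "l5", "l3", "t12", "t8",
            "thigh_r", "thigh_l", "shank_r", "shank_l", "foot_r", "foot_l")
  cols <- list()
  for (s in segs) {
    e <- euler_cols(quats[[s]])
    cols[[paste0("eul_", s, "_z")]] <- e[, 1]
    cols[[paste0("eul_", s, "_x")]] <- e[, 2]
    cols[[paste0("eul_", s, "_y")]] <- e[, 3]
    q <- quats[[s]]
    cols[[paste0("quat_", s, "_w")]] <- q[, 1]
    cols[[paste0("quat_", s, "_x")]] <- q[, 2]
    cols[[paste0("quat_", s, "_y")]] <- q[, 3]
    cols[[paste0("quat_", s, "_z")]] <- q[, 4]
    av <- avel(s); la <- lacc(s)
    for (k in 1:3) {
      ax <- c("x", "y", "z")[k]
      cols[[paste0("avel_", s, "_", ax)]] <- av[, k]
      cols[[paste0("lacc_", s, "_", ax)]] <- la[, k]
    }
  }
  for (j in names(.JOINTS_REAL)) {
    pr <- .JOINTS_REAL[[j]]
    e <- rel_euler(quats[[pr[2]]], quats[[pr[1]]])
    cols[[paste0("jang_", j, "_z")]] <- e[, 1]
    cols[[paste0("jang_", j, "_x")]] <- e[, 2]
    cols[[paste0("jang_", j, "_y")]] <- e[, 3]
  }
  smooth_sig <- function(v) if (degraded) lowpass_zero_lag(v, 10, rate) else v
  tr_f <- trial
  for (cn in c("grf_r_x", "grf_r_y", "grf_r_z", "grf_l_x", "grf_l_y", "grf_l_z",
               "cop_r_x", "cop_r_z", "cop_l_x", "cop_l_z")) {
    tr_f[[cn]] <- smooth_sig(trial[[cn]])
  }
  cols <- c(cols, insole_channels(tr_f, quats$foot_r, quats$foot_l))
  features_tibble(trial, cols, registry, "real")
}

#' Subset a feature matrix by sensor locations
#'
#' Keeps exactly the channels whose required sensor locations are all in
#' `locations`. Joint angles require both adjacent segments' IMUs; the
#' model-based spine segments require pelvis and trunk; bilateral locations
#' always cover both sides.
#'
#' @param fm An `ll_features` tibble.
#' @param locations Non-empty subset of
#'   `c("trunk", "pelvis", "thigh", "shank", "foot", "insole")`.
#' @return The subset `ll_features` (channel order preserved).
#' @export
#' @examples
#' # idealized trunk-only keeps the 3 trunk Euler channels
subset_features <- function(fm, locations) {
  if (length(locations) == 0) abort("`locations` must be non-empty.")
  bad <- setdiff(locations, .LOCATIONS)
  if (length(bad) > 0) abort(sprintf("unknown location token(s): %s.",
                                     paste(bad, collapse = ", ")))
  registry <- attr(fm, "registry")
  keep <- purrr::map_lgl(registry$requires, ~ all(.x %in% locations))
  reg2 <- registry[keep, ]
  out <- fm[, c("participant_id", "task_id", "time", reg2$channel)]
  attr(out, "registry") <- reg2
  attr(out, "provenance") <- attr(fm, "provenance")
  attr(out, "rate") <- attr(fm, "rate")
  class(out) <- c("ll_features", class(out))
  out
}

feature_channels <- function(fm) {
  reg <- attr(fm, "registry")
  if (!is.null(reg)) return(reg$channel)
  setdiff(names(fm), c("participant_id", "task_id", "time", "target", "fold"))
}

#' Fit a per-channel z-score normalizer on training samples
#'
#' @param train A data frame of training samples.
#' @param channels Channels to normalize (default: all registry channels).
#' @return An `ll_normalizer` tibble (`channel`, `mean`, `sd`, `constant`).
#'   Constant channels are flagged and passed through unscaled.
#' @export
fit_normalizer <- function(train, channels = NULL) {
  channels <- channels %||% feature_channels(train)
  if (nrow(train) < 2) abort("need at least 2 training samples.")
  mu <- vapply(channels, function(ch) mean(train[[ch]]), numeric(1))
  sg <- vapply(channels, function(ch) sd(train[[ch]]), numeric(1))
  const <- sg < 1e-12
  out <- tibble::tibble(channel = channels, mean = mu, sd = sg, constant = const)
  class(out) <- c("ll_normalizer", class(out))
  out
}

#' @rdname fit_normalizer
#' @param norm A fitted `ll_normalizer`.
#' @param samples Data frame to scale with the training-fold statistics.
#' @export
apply_normalizer <- function(norm, samples) {
  out <- samples
  for (i in seq_len(nrow(norm))) {
    if (norm$constant[i]) next
    ch <- norm$channel[i]
    out[[ch]] <- (samples[[ch]] - norm$mean[i]) / norm$sd[i]
  }
  out
}
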