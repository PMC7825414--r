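# Trial simulation: keyframe postures from a planar posture solver,
# minimum-jerk time scaling between keyframes, analytic differentiation of
# the interpolant, and ground reaction forces synthesized so every noise-free
# trial is dynamically consistent (whole-body Newton-Euler closure).
#
# Global frame: X anterior, Y up, Z to the participant's right. All sagittal
# posture coordinates are absolute segment tilts from vertical, positive
# when the segment top leans anterior (+X); a tilt phi maps to the rotation
# Rz(-phi). The trunk additionally carries a lateral lean (about X) and an
# axial rotation (about Y) for lateral/diagonal tasks.

.POSTURE_COORDS <- c("phi_sh", "phi_th", "phi_p", "phi_tr",
                     "lam", "psi", "alpha", "chi")

# Style templates: maximum-bend segment tilts (radians) scaled by the bend
# depth s solved per shelf. phi_th is negative: in a squat the hips drop
# behind the knees.
.STYLE_TEMPLATES <- list(
  squat    = c(phi_sh = 0.35, phi_th = -1.70, phi_p = 0.90, phi_tr = 0.90),
  stoop    = c(phi_sh = 0.12, phi_th = -0.25, phi_p = 1.00, phi_tr = 1.50),
  lateral  = c(phi_sh = 0.15, phi_th = -0.90, phi_p = 0.95, phi_tr = 1.30),
  diagonal = c(phi_sh = 0.25, phi_th = -1.20, phi_p = 0.95, phi_tr = 1.20)
)

# Minimum-jerk scalar interpolant through keyframes (zero velocity and
# acceleration at every keyframe), with analytic first and second derivatives.
min_jerk_traj <- function(knot_t, knot_v, time) {
  seg <- pmin(pmax(findInterval(time, knot_t, rightmost.closed = TRUE), 1L),
              length(knot_t) - 1L)
  t0 <- knot_t[seg]; t1 <- knot_t[seg + 1L]
  v0 <- knot_v[seg]; v1 <- knot_v[seg + 1L]
  T <- t1 - t0
  tau <- (time - t0) / T
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  ds <- (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / T
  dds <- (60 * tau - 180 * tau^2 + 120 * tau^3) / T^2
  dv <- v1 - v0
  list(th = v0 + dv * s, dth = dv * ds, ddth = dv * dds)
}

# Shoulder height (m) for bend depth s, sagittal chain only.
shoulder_height <- function(s, tmpl, seg, geom_h) {
  geom_h["ankle"] +
    seg$length[seg$segment == "shank_r"] * cos(s * tmpl[["phi_sh"]]) +
    seg$length[seg$segment == "thigh_r"] * cos(s * tmpl[["phi_th"]]) +
    seg$length[seg$segment == "pelvis"] * cos(s * tmpl[["phi_p"]]) +
    seg$length[seg$segment == "trunk"] * cos(s * tmpl[["phi_tr"]])
}

# Static sagittal CoM (x, m) of the body above the ankles for a set of
# absolute segment tilts, plus the planted feet.
static_com_x <- function(phi, seg, geom_h) {
  len <- setNames(seg$length, seg$segment)
  cf <- setNames(seg$com_frac, seg$segment)
  m <- setNames(seg$mass, seg$segment)
  x_knee <- len["shank_r"] * sin(phi[["phi_sh"]])
  x_hip <- x_knee + len["thigh_r"] * sin(phi[["phi_th"]])
  x_l5s1 <- x_hip + len["pelvis"] * sin(phi[["phi_p"]])
  x_foot <- (0.5 - .GEOM$foot_back) * len["foot_r"]
  xs <- c(
    foot = x_foot,
    shank = (1 - cf[["shank_r"]]) * len["shank_r"] * sin(phi[["phi_sh"]]),
    thigh = x_knee + (1 - cf[["thigh_r"]]) * len["thigh_r"] * sin(phi[["phi_th"]]),
    pelvis = x_hip + cf[["pelvis"]] * len["pelvis"] * sin(phi[["phi_p"]]),
    trunk = x_l5s1 + cf[["trunk"]] * len["trunk"] * sin(phi[["phi_tr"]])
  )
  ms <- c(2 * m[["foot_r"]], 2 * m[["shank_r"]], 2 * m[["thigh_r"]],
          m[["pelvis"]], m[["trunk"]])
  sum(xs * ms) / sum(ms)
}

# Planar posture solver: find the bend depth s and arm depression angle
# alpha that bring the hand to the shelf height, with style-specific joint
# weighting, then balance the posture (static CoM over the foot centers) by
# adjusting the shank tilt. Returns the 8 posture coordinates for one
# keyframe.
solve_posture <- function(anthro, shelf_height, lateral_offset, style,
                          tmpl_scale = rep(1, 4), reach_frac = 0.85,
                          sway = 0) {
  seg <- segment_table(anthro)
  geom_h <- c(ankle = .GEOM$ankle_height * anthro$body_height)
  tmpl <- .STYLE_TEMPLATES[[style]]
  b <- anthro$bend_style %||% 0
  tmpl[["phi_tr"]] <- tmpl[["phi_tr"]] * (1 + 0.30 * b)
  tmpl[["phi_th"]] <- tmpl[["phi_th"]] * (1 - 0.30 * b)
  tmpl <- tmpl * tmpl_scale
  r_arm <- .GEOM$arm_length * anthro$body_height

  target_sh <- shelf_height + reach_frac * r_arm
  f <- function(s) shoulder_height(s, tmpl, seg, geom_h) - target_sh
  s_max <- 1.35
  if (shoulder_height(0, tmpl, seg, geom_h) + 0.95 * r_arm < shelf_height) {
    abort("unreachable shelf for given anthropometry (too high).")
  }
  # `target_sh` is a style preference (how much of the reach the arms
  # carry). If the style cannot bend low enough even at maximum depth, knee
  # flexion is blended in (what a lifter does when a stoop cannot reach);
  # the shelf is unreachable only when even a full deep squat leaves it
  # beyond arm's reach.
  if (f(0) <= 0) {
    s <- 0
    phi <- c(phi_sh = 0, phi_th = 0, phi_p = 0, phi_tr = 0)
  } else if (f(s_max) > 0) {
    deep <- c(phi_sh = 0.30, phi_th = -1.55, phi_p = 0.80, phi_tr = 0.85)
    blend <- function(w) (1 - w) * tmpl + w * deep
    g <- function(w) shoulder_height(s_max, blend(w), seg, geom_h) - target_sh
    if (g(1) > 0) {
      if (shoulder_height(s_max, blend(1), seg, geom_h) - shelf_height >
          0.98 * r_arm) {
        abort("unreachable shelf for given anthropometry (too low).")
      }
      w <- 1
    } else {
      w <- stats::uniroot(g, c(0, 1), tol = 1e-10)$root
    }
    tmpl <- blend(w)
    phi <- s_max * c(phi_sh = tmpl[["phi_sh"]], phi_th = tmpl[["phi_th"]],
                     phi_p = tmpl[["phi_p"]], phi_tr = tmpl[["phi_tr"]])
  } else {
    s <- stats::uniroot(f, c(0, s_max), tol = 1e-10)$root
    phi <- c(phi_sh = s * tmpl[["phi_sh"]], phi_th = s * tmpl[["phi_th"]],
             phi_p = s * tmpl[["phi_p"]], phi_tr = s * tmpl[["phi_tr"]])
  }
  # balance: shift the whole chain about the ankles so the static CoM sits
  # over the foot centers (what a lifter does by moving the hips back);
  # `sway` adds the posture-independent CoP wander real balance exhibits
  x_target <- (0.5 - .GEOM$foot_back) * seg$length[seg$segment == "foot_r"] + sway
  bal <- function(d) {
    p <- phi; p[["phi_sh"]] <- p[["phi_sh"]] + d
    static_com_x(p, seg, geom_h) - x_target
  }
  if (bal(-0.5) * bal(0.5) < 0) {
    d <- stats::uniroot(bal, c(-0.5, 0.5), tol = 1e-10)$root
    phi[["phi_sh"]] <- phi[["phi_sh"]] + d
  }
  len <- setNames(seg$length, seg$segment)
  sh_y <- geom_h[["ankle"]] + len[["shank_r"]] * cos(phi[["phi_sh"]]) +
    len[["thigh_r"]] * cos(phi[["phi_th"]]) + len[["pelvis"]] * cos(phi[["phi_p"]]) +
    len[["trunk"]] * cos(phi[["phi_tr"]])
  alpha <- acos(pmin(1, pmax(-1, (sh_y - shelf_height) / r_arm)))
  psi <- if (lateral_offset != 0) 0.9 * atan2(lateral_offset, 0.45) else 0
  c(phi, lam = 0.35 * psi, psi = psi, alpha = alpha, chi = psi)
}

upright_posture <- function() {
  setNames(rep(0, length(.POSTURE_COORDS)), .POSTURE_COORDS)
}

# Hand direction unit vector u(alpha, chi) and its analytic time derivatives.
# alpha: depression from straight-down; chi: azimuth about Y (toward -Z for
# positive chi... the arm sweeps with the trunk's axial rotation).
hand_direction <- function(a, chi, da, dda, dchi, ddchi) {
  sa <- sin(a); ca <- cos(a); sc <- sin(chi); cc <- cos(chi)
  u <- cbind(sa * cc, -ca, -sa * sc)
  du <- cbind(ca * da * cc - sa * sc * dchi,
              sa * da,
              -ca * da * sc - sa * cc * dchi)
  A <- ca * dda - sa * da^2 - sa * dchi^2
  B <- 2 * ca * da * dchi + sa * ddchi
  ddu <- cbind(cc * A - sc * B,
               ca * da^2 + sa * dda,
               -sc * A - cc * B)
  list(u = u, du = du, ddu = ddu)
}

# child point = parent point + R d, with velocity/acceleration propagation.
offset_point <- function(parent, R, w, al, d) {
  rd <- rotmat_apply(R, d)
  list(
    p = parent$p + rd,
    v = parent$v + cross3(w, rd),
    a = parent$a + cross3(al, rd) + cross3(w, cross3(w, rd))
  )
}

static_point <- function(v, n) {
  m <- mat3_const(v, n)
  z <- matrix(0, n, 3)
  list(p = m, v = z, a = z)
}

# Local inertia tensor diagonal (kg m^2): Y is the longitudinal axis.
segment_inertia_diag <- function(m, L, rog_frac) {
  it <- m * (rog_frac * L)^2
  c(it, m * (0.5 * rog_frac * L)^2, it)
}

# Rate of change of segment angular momentum about its CoM (n x 3).
seg_hdot <- function(R, w, al, I_diag) {
  Rt <- rotmat_transpose(R)
  w_loc <- rotmat_apply(Rt, w)
  al_loc <- rotmat_apply(Rt, al)
  Iw <- rotmat_apply(R, w_loc * mat3_const(I_diag, nrow(R)))
  Ial <- rotmat_apply(R, al_loc * mat3_const(I_diag, nrow(R)))
  Ial + cross3(w, Iw)
}

.SEGMENTS <- c("foot_r", "foot_l", "shank_r", "shank_l",
               "thigh_r", "thigh_l", "pelvis", "trunk")

# Full-chain kinematics from posture coordinate trajectories.
# traj: named list of lists(th, dth, ddth); n samples.
chain_kinematics <- function(anthro, traj, n, width_scale = 1) {
  seg <- segment_table(anthro)
  H <- anthro$body_height
  len <- setNames(seg$length, seg$segment)
  cf <- setNames(seg$com_frac, seg$segment)
  hw <- .GEOM$hip_halfwidth * H * width_scale
  ankle_h <- .GEOM$ankle_height * H
  zero3 <- matrix(0, n, 3)

  rot1z <- function(tr) composite_rotation(
    list(list(axis = "z", th = -tr$th, dth = -tr$dth, ddth = -tr$ddth)), n)

  ankle_r <- static_point(c(0, ankle_h, hw), n)
  ankle_l <- static_point(c(0, ankle_h, -hw), n)

  shank <- rot1z(traj$phi_sh)
  knee_r <- offset_point(ankle_r, shank$R, shank$w, shank$al, c(0, len["shank_r"], 0))
  knee_l <- offset_point(ankle_l, shank$R, shank$w, shank$al, c(0, len["shank_l"], 0))

  thigh <- rot1z(traj$phi_th)
  hip_r <- offset_point(knee_r, thigh$R, thigh$w, thigh$al, c(0, len["thigh_r"], 0))
  hip_l <- offset_point(knee_l, thigh$R, thigh$w, thigh$al, c(0, len["thigh_l"], 0))
  hip_mid <- list(p = (hip_r$p + hip_l$p) / 2, v = (hip_r$v + hip_l$v) / 2,
                  a = (hip_r$a + hip_l$a) / 2)

  pelvis <- rot1z(traj$phi_p)
  l5s1 <- offset_point(hip_mid, pelvis$R, pelvis$w, pelvis$al, c(0, len["pelvis"], 0))

  trunk <- composite_rotation(list(
    list(axis = "z", th = -traj$phi_tr$th, dth = -traj$phi_tr$dth, ddth = -traj$phi_tr$ddth),
    list(axis = "x", th = traj$lam$th, dth = traj$lam$dth, ddth = traj$lam$ddth),
    list(axis = "y", th = traj$psi$th, dth = traj$psi$dth, ddth = traj$psi$ddth)
  ), n)
  shoulder <- offset_point(l5s1, trunk$R, trunk$w, trunk$al, c(0, len["trunk"], 0))

  hd <- hand_direction(traj$alpha$th, traj$chi$th, traj$alpha$dth,
                       traj$alpha$ddth, traj$chi$dth, traj$chi$ddth)
  r_arm <- .GEOM$arm_length * H
  hand <- list(p = shoulder$p + r_arm * hd$u,
               v = shoulder$v + r_arm * hd$du,
               a = shoulder$a + r_arm * hd$ddu)

  # CoM of distal->proximal segments: com_frac is measured from the proximal
  # (upper) end, so the offset from the lower chain point is (1 - com_frac).
  com_foot_off <- function(side) {
    a <- if (side == "r") ankle_r else ankle_l
    fl <- len[paste0("foot_", side)]
    list(p = a$p + mat3_const(c((0.5 - .GEOM$foot_back) * fl, -ankle_h / 2, 0), n),
         v = zero3, a = zero3)
  }
  ident <- list(R = rotmat_identity(n), w = zero3, al = zero3)

  states <- list(
    foot_r = c(ident, list(com = com_foot_off("r"))),
    foot_l = c(ident, list(com = com_foot_off("l"))),
    shank_r = list(R = shank$R, w = shank$w, al = shank$al,
                   com = offset_point(ankle_r, shank$R, shank$w, shank$al,
                                      c(0, (1 - cf["shank_r"]) * len["shank_r"], 0))),
    shank_l = list(R = shank$R, w = shank$w, al = shank$al,
                   com = offset_point(ankle_l, shank$R, shank$w, shank$al,
                                      c(0, (1 - cf["shank_l"]) * len["shank_l"], 0))),
    thigh_r = list(R = thigh$R, w = thigh$w, al = thigh$al,
                   com = offset_point(knee_r, thigh$R, thigh$w, thigh$al,
                                      c(0, (1 - cf["thigh_r"]) * len["thigh_r"], 0))),
    thigh_l = list(R = thigh$R, w = thigh$w, al = thigh$al,
                   com = offset_point(knee_l, thigh$R, thigh$w, thigh$al,
                                      c(0, (1 - cf["thigh_l"]) * len["thigh_l"], 0))),
    pelvis = list(R = pelvis$R, w = pelvis$w, al = pelvis$al,
                  com = offset_point(hip_mid, pelvis$R, pelvis$w, pelvis$al,
                                     c(0, cf["pelvis"] * len["pelvis"], 0))),
    trunk = list(R = trunk$R, w = trunk$w, al = trunk$al,
                 com = offset_point(l5s1, trunk$R, trunk$w, trunk$al,
                                    c(0, cf["trunk"] * len["trunk"], 0)))
  )
  for (s in .SEGMENTS) {
    row <- seg[seg$segment == s, ]
    states[[s]]$m <- row$mass
    states[[s]]$I_diag <- segment_inertia_diag(row$mass, row$length, row$rog_frac)
  }
  list(
    states = states,
    joints = list(ankle_r = ankle_r$p, ankle_l = ankle_l$p,
                  knee_r = knee_r$p, knee_l = knee_l$p,
                  hip_r = hip_r$p, hip_l = hip_l$p,
                  l5s1 = l5s1$p),
    hand = hand
  )
}

set_cols3 <- function(lst, prefix, m, suffixes = c("x", "y", "z")) {
  for (k in seq_along(suffixes)) {
    lst[[paste0(prefix, "_", suffixes[k])]] <- unname(m[, k])
  }
  lst
}

# Assemble the wide per-sample trial tibble from chain kinematics, an object
# timeline, and synthesized ground reaction forces; fill ground truth.
assemble_trial <- function(anthro, participant_id, task_id, rate, time,
                           kin, obj_mass, obj) {
  n <- length(time)
  grf <- whole_body_grf_core(kin$states, obj_mass, obj, anthro)
  cols <- list(time = time)
  for (s in .SEGMENTS) {
    st <- kin$states[[s]]
    q <- quat_from_rotmat(st$R)
    cols[[paste0(s, "_qw")]] <- q[, 1]; cols[[paste0(s, "_qx")]] <- q[, 2]
    cols[[paste0(s, "_qy")]] <- q[, 3]; cols[[paste0(s, "_qz")]] <- q[, 4]
    cols <- set_cols3(cols, paste0(s, "_w"), st$w)
    cols <- set_cols3(cols, paste0(s, "_al"), st$al)
    cols <- set_cols3(cols, paste0(s, "_p"), st$com$p)
    cols <- set_cols3(cols, paste0(s, "_v"), st$com$v)
    cols <- set_cols3(cols, paste0(s, "_a"), st$com$a)
  }
  for (j in names(kin$joints)) cols <- set_cols3(cols, paste0("jc_", j), kin$joints[[j]])
  cols <- set_cols3(cols, "grf_r", grf$grf_r); cols <- set_cols3(cols, "grf_l", grf$grf_l)
  cols <- set_cols3(cols, "cop_r", grf$cop_r); cols <- set_cols3(cols, "cop_l", grf$cop_l)
  cols <- set_cols3(cols, "fm_r", grf$fm_r); cols <- set_cols3(cols, "fm_l", grf$fm_l)
  cols$obj_mass <- obj_mass
  cols <- set_cols3(cols, "obj_p", obj$p)
  cols <- set_cols3(cols, "obj_a", obj$a)
  out <- tibble::new_tibble(cols, nrow = n)
  attr(out, "participant_id") <- participant_id
  attr(out, "task_id") <- task_id
  attr(out, "rate") <- rate
  attr(out, "anthro") <- anthro
  attr(out, "degraded") <- FALSE
  attr(out, "cop_clipped") <- grf$clipped
  class(out) <- c("ll_trial", class(out))
  gt <- bottom_up_lumbar(out)
  out$lumbar_ext_nm <- gt$extension
  out$lumbar_lat_nm <- gt$lateral_bending
  out
}

#' Simulate one manual material handling trial
#'
#' Solves keyframe postures (upright, reach to the origin shelf, carry, reach
#' to the destination shelf, upright) with the planar posture solver,
#' interpolates them with minimum-jerk time scaling, differentiates the
#' interpolant analytically, and synthesizes per-foot ground reaction forces
#' so the trial satisfies whole-body Newton-Euler dynamics exactly. Ground
#' truth L5/S1 moments are filled by bottom-up recursive inverse dynamics.
#'
#' @param anthro An `ll_anthro` record (see [anthropometry()]).
#' @param task An `ll_task` row (see [task_spec()]).
#' @param rate Sampling rate in Hz (>= 20; default 100).
#' @param seed Optional integer seed controlling the small keyframe jitter.
#'   Kinematics do not depend on `box_mass`, so trials simulated with the
#'   same seed and task geometry but different masses are matched in
#'   kinematics.
#' @return A wide per-sample tibble of class `ll_trial` with segment
#'   orientations (unit quaternions), angular velocity/acceleration, CoM
#'   position/velocity/acceleration, joint centers, per-foot GRF + CoP +
#'   free moment, the object mass/position/acceleration timeline, and ground
#'   truth columns `lumbar_ext_nm`, `lumbar_lat_nm`.
#' @export
simulate_trial <- function(anthro, task, rate = 100, seed = NULL) {
  stop_if_not_scalar_number(rate, "rate", positive = TRUE)
  if (rate < 20) abort("`rate` below 20 Hz cannot resolve the motion.")
  task <- as.list(task[1, ])
  n <- round(task$duration * rate) + 1L
  time <- (seq_len(n) - 1) / rate

  # Inter-trial movement variability: joint-angle templates vary by ~12%
  # between repetitions (of the order of the 5-15 degree trial-to-trial
  # variability lifters show), the arm/bend share of the reach varies, and
  # each keyframe's balance point wanders a few centimetres (postural sway).
  jit <- with_seed(seed, list(
    tmpl = rnorm(4, 1, 0.12),
    reach = runif(1, 0.75, 0.95),
    carry_s = runif(1, 0.05, 0.25),
    carry_alpha = runif(1, 0.35, 0.80),
    sway = rnorm(2, 0, 0.02),
    sway_amp = rnorm(3, 0, 0.006),
    sway_freq = runif(3, 0.15, 0.9),
    sway_phase = runif(3, 0, 2 * pi),
    # stance is re-taken every trial: where the CoM sits over the sole and
    # how wide the feet are planted both vary between trials
    stance_dx = rnorm(1, 0, 0.03),
    stance_width = runif(1, 0.85, 1.2)
  ))

  p_origin <- solve_posture(anthro, .SHELF_HEIGHTS[[task$origin_shelf]],
                            task$origin_offset, task$style,
                            tmpl_scale = jit$tmpl, reach_frac = jit$reach,
                            sway = jit$stance_dx + jit$sway[1])
  p_dest <- solve_posture(anthro, .SHELF_HEIGHTS[[task$destination_shelf]],
                          task$destination_offset, task$style,
                          tmpl_scale = jit$tmpl, reach_frac = jit$reach,
                          sway = jit$stance_dx + jit$sway[2])
  p_carry <- upright_posture()
  sq <- .STYLE_TEMPLATES$squat
  p_carry[names(sq)] <- jit$carry_s * sq
  p_carry["alpha"] <- jit$carry_alpha

  knot_t <- c(0, task$pick_time, (task$pick_time + task$place_time) / 2,
              task$place_time, task$duration)
  keyframes <- rbind(upright_posture(), p_origin, p_carry, p_dest, upright_posture())
  traj <- lapply(setNames(.POSTURE_COORDS, .POSTURE_COORDS), function(cc) {
    min_jerk_traj(knot_t, keyframes[, cc], time)
  })

  # continuous ankle-strategy postural sway: band-limited, analytic, and
  # independent of task factors (moves the CoP without changing the task's
  # posture in any informative way)
  for (k in 1:3) {
    wk <- 2 * pi * jit$sway_freq[k]
    ph <- wk * time + jit$sway_phase[k]
    traj$phi_sh$th <- traj$phi_sh$th + jit$sway_amp[k] * sin(ph)
    traj$phi_sh$dth <- traj$phi_sh$dth + jit$sway_amp[k] * wk * cos(ph)
    traj$phi_sh$ddth <- traj$phi_sh$ddth - jit$sway_amp[k] * wk^2 * sin(ph)
  }

  kin <- chain_kinematics(anthro, traj, n, width_scale = jit$stance_width)
  ramp <- function(t0) pmin(1, pmax(0, (time - (t0 - 0.05)) / 0.1))
  obj_mass <- task$box_mass * (ramp(task$pick_time) - ramp(task$place_time))
  assemble_trial(anthro, anthro$participant_id, task$task_id, rate, time,
                 kin, obj_mass, kin$hand)
}

#' Simulate a quiet-standing (or static hold) trial
#'
#' Upright posture with no movement; optionally a held object of given mass
#' at a fixed offset from the L5/S1 joint. Useful as a static-equilibrium
#' reference case.
#'
#' @inheritParams simulate_trial
#' @param duration Duration in s.
#' @param box_mass Held mass in kg (applied for the whole trial).
#' @param box_offset Length-3 offset (m) of the object from the L5/S1 joint
#'   in the global frame.
#' @return An `ll_trial` tibble.
#' @export
quiet_standing_trial <- function(anthro, duration = 2, rate = 100,
                                 box_mass = 0, box_offset = c(0.3, 0, 0)) {
  n <- round(duration * rate) + 1L
  time <- (seq_len(n) - 1) / rate
  zero <- list(th = rep(0, n), dth = rep(0, n), ddth = rep(0, n))
  traj <- lapply(setNames(.POSTURE_COORDS, .POSTURE_COORDS), function(cc) zero)
  kin <- chain_kinematics(anthro, traj, n)
  obj <- list(p = kin$joints$l5s1 + mat3_const(box_offset, n),
              v = matrix(0, n, 3), a = matrix(0, n, 3))
  assemble_trial(anthro, anthro$participant_id, "static", rate, time,
                 kin, rep(box_mass, n), obj)
}

#' Validate trial invariants
#'
#' Checks that all per-sample series share a length, quaternions are unit
#' norm, and (for noise-free trials) that the summed foot GRF matches the
#' whole-body inertial-plus-gravity requirement at every sample.
#'
#' @param trial An `ll_trial`.
#' @param force_tol GRF closure tolerance in N.
#' @return Invisibly `TRUE`; aborts with a message on violation.
#' @export
validate_trial <- function(trial, force_tol = 1e-6) {
  for (s in .SEGMENTS) {
    q <- as.matrix(trial[, paste0(s, "_q", c("w", "x", "y", "z"))])
    if (max(abs(sqrt(rowSums(q^2)) - 1)) > 1e-9) {
      abort(sprintf("non-unit quaternions for segment %s.", s))
    }
  }
  if (!isTRUE(attr(trial, "degraded"))) {
    req <- grf_requirement(trial)
    got <- cbind(trial$grf_r_x + trial$grf_l_x,
                 trial$grf_r_y + trial$grf_l_y,
                 trial$grf_r_z + trial$grf_l_z)
    if (max(abs(req - got)) > force_tol) {
      abort("summed foot GRF does not match the whole-body requirement.")
    }
  }
  invisible(TRUE)
}
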