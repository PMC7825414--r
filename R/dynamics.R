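# Ground-truth lumbar moments via recursive Newton-Euler inverse dynamics.
#
# Bottom-up: from each foot's external wrench (GRF at the CoP plus free
# moment) up through shank, thigh and pelvis to L5/S1. Top-down: over the
# trunk (head + arms lumped) and handheld object about L5/S1. On any
# noise-free trial whose GRFs come from `whole_body_grf` the two recursions
# agree to machine precision; this closure is the module's central oracle.
#
# Sign convention (declared; the underlying physics fixes only the vector):
# the reported moment is the internal moment acting on the trunk at L5/S1.
# Its +Z component is extension (positive when resisting forward flexion),
# its +X component is lateral bending.

trial_anthro <- function(trial) {
  a <- attr(trial, "anthro")
  if (is.null(a)) abort("trial carries no anthropometry attribute.")
  a
}

cols3 <- function(trial, prefix, suffixes = c("x", "y", "z")) {
  as.matrix(trial[, paste0(prefix, "_", suffixes)])
}

trial_quat <- function(trial, s) {
  as.matrix(trial[, paste0(s, "_q", c("w", "x", "y", "z"))])
}

# Reconstruct per-segment dynamic state from a trial's columns.
trial_states <- function(trial) {
  anthro <- trial_anthro(trial)
  seg <- segment_table(anthro)
  out <- list()
  for (s in .SEGMENTS) {
    row <- seg[seg$segment == s, ]
    out[[s]] <- list(
      R = rotmat_from_quat(trial_quat(trial, s)),
      w = cols3(trial, paste0(s, "_w")),
      al = cols3(trial, paste0(s, "_al")),
      com = list(p = cols3(trial, paste0(s, "_p")),
                 a = cols3(trial, paste0(s, "_a"))),
      m = row$mass,
      I_diag = segment_inertia_diag(row$mass, row$length, row$rog_frac)
    )
  }
  out
}

# Whole-body inertial-plus-gravity force requirement (n x 3, N).
grf_requirement <- function(trial) {
  states <- trial_states(trial)
  n <- nrow(trial)
  F <- matrix(0, n, 3)
  for (s in .SEGMENTS) {
    st <- states[[s]]
    F <- F + st$m * (st$com$a - mat3_const(.G_VEC, n))
  }
  F + trial$obj_mass * (cols3(trial, "obj_a") - mat3_const(.G_VEC, n))
}

# Core GRF synthesis over chain states (used by the simulator before the
# trial tibble exists). Returns per-foot force, CoP (on the ground plane)
# and free moment such that the total external wrench matches the
# whole-body Newton-Euler requirement exactly at every sample.
whole_body_grf_core <- function(states, obj_mass, obj, anthro) {
  n <- nrow(states$trunk$com$p)
  g <- mat3_const(.G_VEC, n)
  F_tot <- matrix(0, n, 3)
  M_tot <- matrix(0, n, 3) # about the global origin
  com_num <- matrix(0, n, 3)
  m_sum <- rep(0, n)
  for (s in .SEGMENTS) {
    st <- states[[s]]
    f <- st$m * (st$com$a - g)
    F_tot <- F_tot + f
    M_tot <- M_tot + cross3(st$com$p, f) + seg_hdot(st$R, st$w, st$al, st$I_diag)
    com_num <- com_num + st$m * st$com$p
    m_sum <- m_sum + st$m
  }
  f_obj <- obj_mass * (obj$a - g)
  F_tot <- F_tot + f_obj
  M_tot <- M_tot + cross3(obj$p, f_obj)
  com_num <- com_num + obj_mass * obj$p
  m_sum <- m_sum + obj_mass
  if (any(F_tot[, 2] < 0)) abort("airborne configuration: required vertical force < 0.")

  z_cm <- com_num[, 3] / m_sum
  z_r <- states$foot_r$com$p[1, 3]
  z_l <- states$foot_l$com$p[1, 3]
  share_r <- pmin(1, pmax(0, (z_cm - z_l) / (z_r - z_l)))

  H <- anthro$body_height
  l_f <- 0.152 * H
  # Each foot's reference point on the ground under its CoM; the residual
  # moment about the combined reference splits by load share, and each
  # foot's CoP is solved locally about its own reference.
  ref_r <- c(states$foot_r$com$p[1, 1], 0, states$foot_r$com$p[1, 3])
  ref_l <- c(states$foot_l$com$p[1, 1], 0, states$foot_l$com$p[1, 3])
  ref_mix <- outer(share_r, ref_r) + outer(1 - share_r, ref_l)
  M_res <- M_tot - cross3(ref_mix, F_tot)
  foot_wrench <- function(share, ref) {
    Ff <- F_tot * share
    Mloc <- M_res * share
    fy <- Ff[, 2]
    ok <- fy > 1e-9
    dx <- ifelse(ok, Mloc[, 3] / fy, 0)
    dz <- ifelse(ok, -Mloc[, 1] / fy, 0)
    dxc <- pmin(0.5 * l_f, pmax(-0.5 * l_f, dx))
    dzc <- pmin(0.04, pmax(-0.04, dz))
    clipped <- sum(dxc != dx | dzc != dz)
    cop <- cbind(ref[1] + dxc, rep(0, length(fy)), ref[3] + dzc)
    # whatever the CoP cannot carry stays as a free-moment couple so the
    # total external wrench is always exact
    fm <- Mloc + cross3(mat3_const(ref, length(fy)), Ff) - cross3(cop, Ff)
    list(F = Ff, cop = cop, fm = fm, clipped = clipped)
  }
  wr <- foot_wrench(share_r, ref_r)
  wl <- foot_wrench(1 - share_r, ref_l)
  if (wr$clipped + wl$clipped > 0) {
    warn(sprintf("center of pressure clipped to the support polygon at %d samples.",
                 wr$clipped + wl$clipped), class = "ll_cop_clipped")
  }
  list(grf_r = wr$F, grf_l = wl$F, cop_r = wr$cop, cop_l = wl$cop,
       fm_r = wr$fm, fm_l = wl$fm, clipped = wr$clipped + wl$clipped)
}

#' Synthesize dynamically consistent per-foot ground reaction forces
#'
#' Computes the whole-body inertial-plus-gravity wrench from the trial's
#' segment kinematics and object timeline, splits it between the feet with a
#' frontal-plane lever rule on the combined centre of mass (clipped to
#' \[0, 1\]), and solves each foot's centre of pressure and free moment so the
#' total external wrench is exact. CoPs are clipped to the support polygon
#' with a warning; any clipped moment is retained as a free-moment couple so
#' dynamic closure is never violated.
#'
#' @param trial An `ll_trial`.
#' @return A tibble with per-foot GRF, CoP and free-moment columns
#'   (`grf_r_x`, ..., `fm_l_z`), one row per sample.
#' @export
whole_body_grf <- function(trial) {
  states <- trial_states(trial)
  obj <- list(p = cols3(trial, "obj_p"), a = cols3(trial, "obj_a"))
  res <- whole_body_grf_core(states, trial$obj_mass, obj, trial_anthro(trial))
  out <- list()
  for (nm in c("grf_r", "grf_l", "cop_r", "cop_l", "fm_r", "fm_l")) {
    out <- set_cols3(out, nm, res[[nm]])
  }
  tibble::as_tibble(out)
}

moment_series <- function(time, extension, lateral, rate, units, source) {
  out <- tibble::tibble(time = time, extension = extension,
                        lateral_bending = lateral)
  attr(out, "rate") <- rate
  attr(out, "units") <- units
  attr(out, "source") <- source
  class(out) <- c("ll_moments", class(out))
  out
}

# One Newton-Euler step: proximal wrench of a segment given distal wrenches.
# dists: list of list(F, M, r) applied to this segment at points r.
ne_step <- function(m, com_p, com_a, hdot, r_prox, dists) {
  n <- nrow(com_p)
  g <- mat3_const(.G_VEC, n)
  F_d <- matrix(0, n, 3)
  M_d <- matrix(0, n, 3)
  for (d in dists) {
    F_d <- F_d + d$F
    M_d <- M_d + d$M + cross3(d$r - com_p, d$F)
  }
  F_p <- m * com_a - m * g - F_d
  M_p <- hdot - cross3(r_prox - com_p, F_p) - M_d
  list(F = F_p, M = M_p)
}

#' Bottom-up lumbar moment by recursive Newton-Euler
#'
#' Recurses from each foot's external wrench (GRF at its centre of pressure
#' plus free moment) up through shank, thigh and pelvis to the L5/S1 joint,
#' and reports the internal moment on the trunk: extension (+Z) and lateral
#' bending (+X) components in N m.
#'
#' @param trial An `ll_trial` with complete kinematics, GRFs and joint
#'   centers.
#' @return An `ll_moments` tibble (`time`, `extension`, `lateral_bending`)
#'   in N m with `source = "lab_truth"`.
#' @export
bottom_up_lumbar <- function(trial) {
  states <- trial_states(trial)
  if (!all(is.finite(as.matrix(trial[, grep("^(grf|cop|fm|jc)_", names(trial))])))) {
    abort("non-finite forces or joint centers in trial.")
  }
  n <- nrow(trial)
  hd <- function(s) seg_hdot(states[[s]]$R, states[[s]]$w, states[[s]]$al,
                             states[[s]]$I_diag)
  leg <- function(side) {
    foot <- states[[paste0("foot_", side)]]
    shank <- states[[paste0("shank_", side)]]
    thigh <- states[[paste0("thigh_", side)]]
    ankle <- cols3(trial, paste0("jc_ankle_", side))
    knee <- cols3(trial, paste0("jc_knee_", side))
    hip <- cols3(trial, paste0("jc_hip_", side))
    w_ankle <- ne_step(foot$m, foot$com$p, foot$com$a, hd(paste0("foot_", side)),
                       ankle,
                       list(list(F = cols3(trial, paste0("grf_", side)),
                                 M = cols3(trial, paste0("fm_", side)),
                                 r = cols3(trial, paste0("cop_", side)))))
    w_knee <- ne_step(shank$m, shank$com$p, shank$com$a, hd(paste0("shank_", side)),
                      knee, list(list(F = -w_ankle$F, M = -w_ankle$M, r = ankle)))
    w_hip <- ne_step(thigh$m, thigh$com$p, thigh$com$a, hd(paste0("thigh_", side)),
                     hip, list(list(F = -w_knee$F, M = -w_knee$M, r = knee)))
    list(F = w_hip$F, M = w_hip$M, r = hip)
  }
  right <- leg("r"); left <- leg("l")
  pelvis <- states$pelvis
  w_l5s1 <- ne_step(pelvis$m, pelvis$com$p, pelvis$com$a, hd("pelvis"),
                    cols3(trial, "jc_l5s1"),
                    list(list(F = -right$F, M = -right$M, r = right$r),
                         list(F = -left$F, M = -left$M, r = left$r)))
  # w_l5s1 is the wrench the trunk applies to the pelvis; the internal moment
  # on the trunk is its negative.
  moment_series(trial$time, -w_l5s1$M[, 3], -w_l5s1$M[, 1],
                attr(trial, "rate"), units = "Nm", source = "lab_truth")
}

#' Top-down lumbar moment (independent oracle)
#'
#' Newton-Euler over the trunk (head + arms lumped) and handheld object
#' gravity and inertial wrenches about L5/S1. Equals [bottom_up_lumbar()] to
#' machine precision on any noise-free trial whose GRFs satisfy whole-body
#' closure.
#'
#' @inheritParams bottom_up_lumbar
#' @return An `ll_moments` tibble in N m.
#' @export
top_down_lumbar <- function(trial) {
  states <- trial_states(trial)
  n <- nrow(trial)
  g <- mat3_const(.G_VEC, n)
  tr <- states$trunk
  r_j <- cols3(trial, "jc_l5s1")
  M <- seg_hdot(tr$R, tr$w, tr$al, tr$I_diag) +
    cross3(tr$com$p - r_j, tr$m * (tr$com$a - g)) +
    cross3(cols3(trial, "obj_p") - r_j,
           trial$obj_mass * (cols3(trial, "obj_a") - g))
  moment_series(trial$time, M[, 3], M[, 1], attr(trial, "rate"),
                units = "Nm", source = "lab_truth")
}

#' Normalize a moment series to body weight x body height units
#'
#' Divides each sample by `body_mass * g * body_height` (the study's
#' reporting unit); [denormalize_bwbh()] inverts it.
#'
#' @param series An `ll_moments` tibble in N m.
#' @param anthro The participant's `ll_anthro`.
#' @return The series in BW x BH units (`units` attribute `"BWBH"`).
#' @export
#' @examples
#' a <- anthropometry("p", 79, 1.8)
#' m <- quiet_standing_trial(a, duration = 0.05, box_mass = 10,
#'                           box_offset = c(0.4, 0, 0))
#' normalize_bwbh(bottom_up_lumbar(m), a)$extension[1]
normalize_bwbh <- function(series, anthro) {
  if (!identical(attr(series, "units"), "Nm")) abort("series must be in Nm.")
  k <- bwbh(anthro)
  if (k <= 0) abort("non-positive body mass or height.")
  moment_series(series$time, series$extension / k, series$lateral_bending / k,
                attr(series, "rate"), units = "BWBH", source = attr(series, "source"))
}

#' @rdname normalize_bwbh
#' @export
denormalize_bwbh <- function(series, anthro) {
  if (!identical(attr(series, "units"), "BWBH")) abort("series must be in BWBH.")
  k <- bwbh(anthro)
  moment_series(series$time, series$extension * k, series$lateral_bending * k,
                attr(series, "rate"), units = "Nm", source = attr(series, "source"))
}
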