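# Inverse dynamics: bottom-up vs top-down closure, static closed forms,
# frame independence, superposition, and unit normalization.

test_that("bottom-up and top-down recursions agree on simulated trials", {
  a <- ref_anthro()
  set.seed(31)
  for (style in c("squat", "stoop", "lateral")) {
    task <- task_spec("t", sample(c(5, 15, 23), 1), "low", "high", style = style)
    tr <- suppressWarnings(simulate_trial(a, task, seed = sample.int(1e6, 1)))
    bu <- bottom_up_lumbar(tr)
    td <- top_down_lumbar(tr)
    expect_lt(rel_rms(bu$extension, td$extension), 1e-9)
    expect_lt(rel_rms(bu$lateral_bending, td$lateral_bending) *
                (sd(td$lateral_bending) > 1e-6), 1e-9)
  }
})

test_that("upright stance with nothing held produces zero lumbar moment", {
  qt <- quiet_standing_trial(ref_anthro(), duration = 0.3)
  expect_lt(max(abs(qt$lumbar_ext_nm)), 1e-9)
  expect_lt(max(abs(qt$lumbar_lat_nm)), 1e-9)
})

test_that("static closed forms: anterior and lateral point loads", {
  a <- ref_anthro()
  # 10 kg held 0.4 m anterior of L5/S1 -> extension moment m g x
  hold <- quiet_standing_trial(a, duration = 0.1, box_mass = 10,
                               box_offset = c(0.4, 0, 0))
  expect_equal(hold$lumbar_ext_nm[3], 10 * 9.81 * 0.4, tolerance = 1e-9)
  expect_lt(max(abs(hold$lumbar_lat_nm)), 1e-9)

  # 10 kg held 0.3 m to the left -> lateral bending moment m g |z|
  lat <- quiet_standing_trial(a, duration = 0.1, box_mass = 10,
                              box_offset = c(0, 0, -0.3))
  expect_equal(lat$lumbar_lat_nm[3], 10 * 9.81 * 0.3, tolerance = 1e-9)
  expect_lt(max(abs(lat$lumbar_ext_nm)), 1e-9)

  # trunk CoM (40 kg) at 0.1 m anterior plus 10 kg at 0.4 m: top-down closed
  # form on a hand-displaced trunk
  a40 <- anthropometry("p40", body_mass = 40 / 0.536, body_height = 1.8)
  tr <- quiet_standing_trial(a40, duration = 0.1, box_mass = 10,
                             box_offset = c(0.4, 0, 0))
  tr$trunk_p_x <- tr$jc_l5s1_x + 0.1
  td <- top_down_lumbar(tr)
  expect_equal(td$extension[2], 40 * 9.81 * 0.1 + 10 * 9.81 * 0.4,
               tolerance = 1e-9)
  # re-synthesizing consistent GRFs makes the bottom-up recursion agree
  grf <- suppressWarnings(whole_body_grf(tr))
  for (cn in names(grf)) tr[[cn]] <- grf[[cn]]
  expect_equal(bottom_up_lumbar(tr)$extension[2], 78.48, tolerance = 1e-9)
})

test_that("object load superposes linearly at matched kinematics", {
  a <- ref_anthro()
  t0 <- task_spec("t", 0, "low", "mid", style = "squat")
  t23 <- task_spec("t", 23, "low", "mid", style = "squat")
  tr0 <- suppressWarnings(simulate_trial(a, t0, seed = 17))
  tr23 <- suppressWarnings(simulate_trial(a, t23, seed = 17))
  # identical kinematics by construction
  expect_identical(tr0$trunk_qw, tr23$trunk_qw)
  diff <- tr23$lumbar_ext_nm - tr0$lumbar_ext_nm
  g <- c(0, -9.81, 0)
  r <- cbind(tr23$obj_p_x - tr23$jc_l5s1_x, tr23$obj_p_y - tr23$jc_l5s1_y,
             tr23$obj_p_z - tr23$jc_l5s1_z)
  f <- tr23$obj_mass * cbind(tr23$obj_a_x - g[1], tr23$obj_a_y - g[2],
                             tr23$obj_a_z - g[3])
  pred <- r[, 1] * f[, 2] - r[, 2] * f[, 1] # z component of r x f
  expect_equal(diff, pred, tolerance = 1e-6)
})

test_that("peak extension moment is non-decreasing in box mass", {
  a <- ref_anthro()
  peaks <- vapply(c(0, 5, 10, 15, 23), function(m) {
    tr <- suppressWarnings(simulate_trial(
      a, task_spec("t", m, "low", "mid", style = "squat"), seed = 7))
    max(tr$lumbar_ext_nm)
  }, numeric(1))
  expect_true(all(diff(peaks) >= 0))
})

test_that("a rigid rotation about vertical leaves the horizontal moment magnitude", {
  tr <- ref_trial()
  th <- 0.7
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
              3, 3, byrow = TRUE)
  qrot <- c(cos(th / 2), 0, sin(th / 2), 0)
  rot <- tibble::as_tibble(tr)
  vec_prefixes <- c(
    paste0(rep(c("foot_r", "foot_l", "shank_r", "shank_l", "thigh_r",
                 "thigh_l", "pelvis", "trunk"), each = 5),
           c("_w", "_al", "_p", "_v", "_a")),
    paste0("jc_", c("ankle_r", "ankle_l", "knee_r", "knee_l", "hip_r",
                    "hip_l", "l5s1")),
    "grf_r", "grf_l", "cop_r", "cop_l", "fm_r", "fm_l", "obj_p", "obj_a")
  for (p in vec_prefixes) {
    v <- as.matrix(rot[, paste0(p, c("_x", "_y", "_z"))]) %*% t(R)
    rot[[paste0(p, "_x")]] <- v[, 1]
    rot[[paste0(p, "_y")]] <- v[, 2]
    rot[[paste0(p, "_z")]] <- v[, 3]
  }
  for (s in c("foot_r", "foot_l", "shank_r", "shank_l", "thigh_r", "thigh_l",
              "pelvis", "trunk")) {
    q <- as.matrix(rot[, paste0(s, c("_qw", "_qx", "_qy", "_qz"))])
    qr <- matrix(qrot, nrow(q), 4, byrow = TRUE)
    qn <- cbind(
      qr[, 1] * q[, 1] - qr[, 2] * q[, 2] - qr[, 3] * q[, 3] - qr[, 4] * q[, 4],
      qr[, 1] * q[, 2] + qr[, 2] * q[, 1] + qr[, 3] * q[, 4] - qr[, 4] * q[, 3],
      qr[, 1] * q[, 3] - qr[, 2] * q[, 4] + qr[, 3] * q[, 1] + qr[, 4] * q[, 2],
      qr[, 1] * q[, 4] + qr[, 2] * q[, 3] - qr[, 3] * q[, 2] + qr[, 4] * q[, 1])
    rot[[paste0(s, "_qw")]] <- qn[, 1]; rot[[paste0(s, "_qx")]] <- qn[, 2]
    rot[[paste0(s, "_qy")]] <- qn[, 3]; rot[[paste0(s, "_qz")]] <- qn[, 4]
  }
  for (at in c("participant_id", "task_id", "rate", "anthro", "degraded")) {
    attr(rot, at) <- attr(tr, at)
  }
  class(rot) <- class(tr)
  m0 <- bottom_up_lumbar(tr)
  m1 <- bottom_up_lumbar(rot)
  mag0 <- sqrt(m0$extension^2 + m0$lateral_bending^2)
  mag1 <- sqrt(m1$extension^2 + m1$lateral_bending^2)
  expect_lt(max(abs(mag0 - mag1)) / max(mag0), 1e-9)
})

test_that("GRF synthesis reproduces the stored trial forces and flags airborne", {
  tr <- ref_trial()
  grf <- suppressWarnings(whole_body_grf(tr))
  expect_equal(grf$grf_r_y, tr$grf_r_y, tolerance = 1e-12)
  expect_equal(grf$cop_l_x, tr$cop_l_x, tolerance = 1e-12)

  bad <- tibble::as_tibble(ref_trial())
  for (at in c("participant_id", "task_id", "rate", "anthro", "degraded")) {
    attr(bad, at) <- attr(tr, at)
  }
  class(bad) <- class(tr)
  bad$trunk_a_y <- bad$trunk_a_y - 100 # free fall and then some
  expect_error(suppressWarnings(whole_body_grf(bad)), "airborne")
})

test_that("BW x BH normalization matches hand arithmetic and round-trips", {
  a <- ref_anthro()
  m <- quiet_standing_trial(a, duration = 0.05, box_mass = 10,
                            box_offset = c(0.4, 0, 0))
  series <- bottom_up_lumbar(m)
  norm <- normalize_bwbh(series, a)
  expect_equal(norm$extension[1], 39.24 / (79 * 9.81 * 1.8), tolerance = 1e-12)
  expect_equal(normalize_bwbh(moment_series_for_test(77.5), a)$extension[1],
               77.5 / (79 * 9.81 * 1.8), tolerance = 1e-12)
  back <- denormalize_bwbh(norm, a)
  expect_equal(back$extension, series$extension, tolerance = 1e-12)
  expect_error(normalize_bwbh(norm, a), "Nm")
})
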