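# Cohort sampling, task battery, trial simulation, and sensor degradation.

test_that("cohort sampling follows the stated population and is seeded", {
  cohort <- sample_cohort(10, seed = 1)
  expect_equal(nrow(cohort), 10)
  expect_true(all(cohort$body_height >= 1.5 & cohort$body_height <= 2.1))
  expect_true(all(cohort$body_mass >= 45 & cohort$body_mass <= 130))
  expect_identical(cohort, sample_cohort(10, seed = 1))
  expect_false(identical(cohort$body_mass, sample_cohort(10, seed = 2)$body_mass))

  # degenerate spread pins every participant at the mean
  fixed <- sample_cohort(5, height_sd = 0, mass_sd = 0, seed = 3)
  expect_equal(fixed$body_height, rep(1.8, 5))
  expect_equal(fixed$body_mass, rep(79, 5))

  # Monte-Carlo check of the truncated-normal moments
  big <- sample_cohort(10000, seed = 7)
  expect_lt(abs(mean(big$body_mass) - 79), 0.5)
  expect_lt(abs(mean(big$body_height) - 1.8), 0.01)

  expect_error(sample_cohort(0), "n")
  expect_error(sample_cohort(3, mass_sd = -1), ">= 0")
  expect_error(sample_cohort(3, mass_bounds = c(100, 50), seed = 1), "inverted")
})

test_that("segment mass fractions sum to one and BW/BH derive correctly", {
  sp <- default_segment_params()
  expect_equal(sum(sp$mass_frac), 1, tolerance = 1e-12)
  a <- ref_anthro()
  expect_equal(body_weight(a), 79 * 9.81)
  expect_equal(bwbh(a), 79 * 9.81 * 1.8)
})

test_that("task battery is the shuffled cross product of its factors", {
  b100 <- build_task_battery(repetitions = 1)
  expect_equal(nrow(b100), 100) # 5 masses x 5 shelf pairs x 4 styles
  b400 <- build_task_battery()
  expect_equal(nrow(b400), 400)
  expect_identical(b400, build_task_battery())

  one <- build_task_battery(masses = 10, shelf_pairs = list(c("low", "mid")),
                            styles = "squat", repetitions = 1)
  expect_equal(nrow(one), 1)

  expect_error(build_task_battery(masses = numeric(0)), "non-empty")
  expect_error(task_spec("t", 30, "low", "mid"), "box_mass")
  expect_error(task_spec("t", 5, "low", "mid", pick_time = 3, place_time = 2),
               "pick_time")
})

test_that("zero-mass tasks carry no object load anywhere in the trial", {
  task <- task_spec("t0", 0, "low", "mid", style = "stoop")
  tr <- suppressWarnings(simulate_trial(ref_anthro(), task, seed = 1))
  expect_true(all(tr$obj_mass == 0))
})

test_that("static trials satisfy static equilibrium exactly", {
  a <- ref_anthro()
  qt <- quiet_standing_trial(a, duration = 0.5)
  expect_equal(qt$grf_r_y + qt$grf_l_y, rep(79 * 9.81, nrow(qt)),
               tolerance = 1e-10)
  # symmetric stance: each foot carries half
  expect_equal(qt$grf_r_y, qt$grf_l_y, tolerance = 1e-9)

  hold <- quiet_standing_trial(a, duration = 0.5, box_mass = 10)
  expect_equal(hold$grf_r_y + hold$grf_l_y, rep((79 + 10) * 9.81, nrow(hold)),
               tolerance = 1e-9)
})

test_that("stoop flexes the trunk more than squat for the same shelf pair", {
  a <- ref_anthro()
  peak_flex <- function(style) {
    tr <- suppressWarnings(simulate_trial(
      a, task_spec("t", 10, "low", "mid", style = style), seed = 5))
    f <- build_idealized_features(tr)
    max(f$eul_trunk_z * -1) # forward lean is a negative Z Euler angle
  }
  expect_gt(peak_flex("stoop"), peak_flex("squat"))
})

test_that("trial simulation is deterministic and validates its invariants", {
  a <- ref_anthro()
  task <- task_spec("t", 15, "mid", "high", style = "diagonal")
  t1 <- suppressWarnings(simulate_trial(a, task, seed = 9))
  t2 <- suppressWarnings(simulate_trial(a, task, seed = 9))
  expect_identical(tibble::as_tibble(t1), tibble::as_tibble(t2))
  expect_true(validate_trial(t1))
  expect_error(simulate_trial(a, task, rate = 10), "20 Hz")
})

test_that("zero noise config degrades nothing; nonzero is selective", {
  tr <- ref_trial()
  expect_identical(degrade_to_real(tr, noise_config_zero(), seed = 1), tr)

  insole_only <- noise_config(insole_gain_sd = 0.1, insole_additive_sd = 5,
                              cop_sd = 0.003, imu_angle_bias_sd = 0,
                              imu_angle_white_sd = 0)
  d <- degrade_to_real(tr, insole_only, seed = 2)
  expect_identical(d$trunk_qw, tr$trunk_qw) # orientations untouched
  expect_false(identical(d$grf_r_y, tr$grf_r_y))
  expect_identical(d$lumbar_ext_nm, tr$lumbar_ext_nm) # ground truth untouched

  imu_only <- noise_config(0, 0, Inf, 0, 1, 0.5)
  d2 <- degrade_to_real(tr, imu_only, seed = 3)
  expect_identical(d2$grf_r_y, tr$grf_r_y)
  expect_false(identical(d2$trunk_qw, tr$trunk_qw))

  expect_identical(degrade_to_real(tr, insole_only, seed = 7),
                   degrade_to_real(tr, insole_only, seed = 7))
  expect_error(noise_config(insole_saturation = -5), "saturation")
})

test_that("per-trial insole gain noise has the configured spread", {
  tr <- quiet_standing_trial(ref_anthro(), duration = 0.2)
  cfg <- noise_config(insole_gain_sd = 0.1, insole_additive_sd = 0,
                      cop_sd = 0, imu_angle_bias_sd = 0, imu_angle_white_sd = 0)
  ratios <- vapply(1:1000, function(s) {
    d <- degrade_to_real(tr, cfg, seed = s)
    mean(d$grf_r_y) / mean(tr$grf_r_y)
  }, numeric(1))
  expect_lt(abs(sd(ratios) - 0.1), 0.015)
  expect_lt(abs(mean(ratios) - 1), 0.01)
})

test_that("degraded quaternions stay unit norm", {
  d <- degrade_to_real(ref_trial(), noise_config(), seed = 4)
  q <- as.matrix(d[, c("trunk_qw", "trunk_qx", "trunk_qy", "trunk_qz")])
  expect_lt(max(abs(sqrt(rowSums(q^2)) - 1)), 1e-9)
})
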