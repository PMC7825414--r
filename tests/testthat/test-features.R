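# Channel registries, feature builders, subsetting, and z-score
# normalization.

test_that("channel registries reproduce the published channel counts", {
  ideal <- channel_registry("idealized")
  expect_equal(nrow(ideal), 51)
  expect_equal(sum(ideal$kind == "euler_angle"), 24)
  expect_equal(sum(ideal$kind == "joint_angle"), 21)
  expect_equal(sum(ideal$kind == "normal_force"), 2)
  expect_equal(sum(ideal$kind %in% c("cop_x", "cop_y")), 4)

  real <- channel_registry("real")
  expect_equal(nrow(real), 179)
  counts <- table(real$kind)
  expect_equal(unname(counts[["euler_angle"]]), 33)
  expect_equal(unname(counts[["quaternion"]]), 44)
  expect_equal(unname(counts[["angular_velocity"]]), 33)
  expect_equal(unname(counts[["linear_acceleration"]]), 33)
  expect_equal(unname(counts[["joint_angle"]]), 30)
  expect_equal(unname(counts[["normal_force"]]), 2)
})

test_that("feature builders emit the full registry with no missing values", {
  tr <- ref_trial()
  fi <- build_idealized_features(tr)
  expect_equal(setdiff(names(fi), c("participant_id", "task_id", "time")),
               channel_registry("idealized")$channel)
  expect_false(anyNA(fi))

  fr <- build_real_features(degrade_to_real(tr, noise_config(), seed = 2))
  expect_equal(setdiff(names(fr), c("participant_id", "task_id", "time")),
               channel_registry("real")$channel)
  expect_false(anyNA(fr))
  # quaternion channels remain unit norm after degradation + filtering
  for (s in c("t8", "l3", "foot_r")) {
    q <- as.matrix(fr[, paste0("quat_", s, "_", c("w", "x", "y", "z"))])
    expect_lt(max(abs(sqrt(rowSums(q^2)) - 1)), 1e-6)
  }
})

test_that("zero-noise real features agree with their idealized counterparts", {
  tr <- ref_trial()
  fi <- build_idealized_features(tr)
  fr <- build_real_features(tr) # never degraded -> filters bypassed
  expect_equal(fr$eul_t8_z, fi$eul_trunk_z, tolerance = 1e-12)
  expect_equal(fr$eul_pelvis_z, fi$eul_pelvis_z, tolerance = 1e-12)
  expect_equal(fr$ins_force_r, fi$ins_force_r, tolerance = 1e-12)
  expect_equal(fr$ins_cop_l_x, fi$ins_cop_l_x, tolerance = 1e-12)
})

test_that("quiet standing yields constant joint-angle channels", {
  f <- build_idealized_features(quiet_standing_trial(ref_anthro(), 0.3))
  jang <- grep("^jang_", names(f), value = TRUE)
  spreads <- vapply(jang, function(ch) diff(range(f[[ch]])), numeric(1))
  expect_true(all(spreads < 1e-12))
})

test_that("the trunk sagittal channel tracks a flexion ramp monotonically", {
  a <- ref_anthro()
  tr <- suppressWarnings(simulate_trial(
    a, task_spec("t", 5, "low", "low", style = "stoop"), seed = 3))
  f <- build_idealized_features(tr)
  # descent phase: upright -> full stoop at the pick keyframe
  pick_idx <- round(0.25 * (nrow(f) - 1)) + 1
  descent <- -f$eul_trunk_z[1:pick_idx] # forward lean, positive
  expect_true(all(diff(descent) > -1e-9))
  expect_gt(descent[pick_idx], 1) # deep stoop exceeds ~57 degrees
})

test_that("location subsetting follows the channel-ownership rule", {
  tr <- ref_trial()
  fi <- build_idealized_features(tr)
  expect_equal(lumbarload:::feature_channels(subset_features(fi, "trunk")),
               c("eul_trunk_z", "eul_trunk_x", "eul_trunk_y"))
  expect_equal(length(lumbarload:::feature_channels(subset_features(fi, "insole"))), 6)
  # trunk + pelvis unlocks the lumbar joint angles
  tp <- lumbarload:::feature_channels(subset_features(fi, c("trunk", "pelvis")))
  expect_true(all(c("jang_lumbar_z", "eul_pelvis_x") %in% tp))
  # full set is the identity
  full <- subset_features(fi, c("trunk", "pelvis", "thigh", "shank", "foot",
                                "insole"))
  expect_equal(names(full), names(fi))
  expect_error(subset_features(fi, character(0)), "non-empty")
  expect_error(subset_features(fi, "wrist"), "unknown location")
})

test_that("subsetting a union equals the union of subsets for disjoint sets", {
  fi <- build_idealized_features(ref_trial())
  chans <- function(locs) lumbarload:::feature_channels(subset_features(fi, locs))
  a <- chans("trunk"); b <- chans("insole")
  expect_length(intersect(a, b), 0)
  expect_setequal(chans(c("trunk", "insole")), union(a, b))
})

test_that("real trunk-only subset carries the 13 T8 channels", {
  fr <- build_real_features(ref_trial())
  tr_only <- lumbarload:::feature_channels(subset_features(fr, "trunk"))
  expect_length(tr_only, 13) # 3 Euler + 4 quaternion + 3 ang vel + 3 lin acc
  expect_true(all(grepl("_t8_", tr_only)))
})

test_that("z-score normalizer uses train statistics only", {
  set.seed(8)
  train <- tibble::tibble(a = rnorm(200, 5, 2), b = rnorm(200, -1, 0.5),
                          c = rep(3, 200))
  norm <- fit_normalizer(train, c("a", "b", "c"))
  scaled <- apply_normalizer(norm, train)
  expect_lt(max(abs(c(mean(scaled$a), mean(scaled$b)))), 1e-9)
  expect_lt(max(abs(c(sd(scaled$a), sd(scaled$b)) - 1)), 1e-9)
  # constant channel flagged and passed through
  expect_true(norm$constant[norm$channel == "c"])
  expect_equal(scaled$c, train$c)
  # a shifted test fold keeps its shift (no leakage of test statistics)
  test <- tibble::tibble(a = rnorm(200, 9, 2), b = rnorm(200, -1, 0.5),
                         c = rep(3, 200))
  test_scaled <- apply_normalizer(norm, test)
  expect_gt(mean(test_scaled$a), 1)
  expect_error(fit_normalizer(train[1, ], c("a")), "at least 2")
})
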