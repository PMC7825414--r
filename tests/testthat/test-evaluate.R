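# Accuracy metrics, permutation importance, unit conversions, and the
# paired signed-rank test.

test_that("r2 definition matches hand arithmetic and its edge cases", {
  d <- tibble::tibble(participant_id = "p", target = c(1, 2, 3, 4),
                      prediction = c(1, 2, 3, 5))
  expect_equal(r2_by_participant(d)$r2, 0.8)

  perfect <- tibble::tibble(participant_id = "p", target = 1:10,
                            prediction = 1:10)
  expect_equal(r2_by_participant(perfect)$r2, 1)

  at_mean <- tibble::tibble(participant_id = "p", target = c(1, 2, 3),
                            prediction = rep(2, 3))
  expect_equal(r2_by_participant(at_mean)$r2, 0)

  flat <- tibble::tibble(participant_id = "p", target = rep(1, 4),
                         prediction = 1:4)
  expect_error(r2_by_participant(flat), "zero-variance")
})

test_that("r2 is invariant to a common additive shift of both series", {
  set.seed(4)
  d <- tibble::tibble(participant_id = rep(c("a", "b"), each = 50),
                      target = rnorm(100), prediction = rnorm(100, 0, 0.5))
  shifted <- dplyr::mutate(d, target = target + 3.7, prediction = prediction + 3.7)
  expect_equal(r2_by_participant(shifted)$r2, r2_by_participant(d)$r2,
               tolerance = 1e-9)
})

test_that("RMSE conversion to newton-metres uses cohort means", {
  cohort <- tibble::tibble(body_mass = 79, body_height = 1.8)
  r <- rmse_moment(rep(0.01, 50), rep(0, 50), cohort)
  expect_equal(r$rmse_bwbh, 0.01)
  expect_equal(r$rmse_nm, 0.01 * 79 * 9.81 * 1.8, tolerance = 1e-12)
  # homogeneity: doubling all errors doubles both values
  r2x <- rmse_moment(rep(0.02, 50), rep(0, 50), cohort)
  expect_equal(r2x$rmse_bwbh, 2 * r$rmse_bwbh)
  expect_equal(r2x$rmse_nm, 2 * r$rmse_nm)
  expect_error(rmse_moment(numeric(0), numeric(0), cohort), "empty")
})

test_that("thresholded MAPE includes only samples above the threshold", {
  expect_equal(mape_thresholded(c(1, 1), c(1, 1), 0.05), 0)
  targets <- c(0.2, 0.4); preds <- targets * 0.9
  expect_equal(mape_thresholded(preds, targets, 0.05), 10, tolerance = 1e-12)
  # only 1 of 3 samples exceeds the threshold; MAPE computed on it alone
  t3 <- c(0.01, 0.04, 0.2); p3 <- c(5, 5, 0.25)
  expect_equal(mape_thresholded(p3, t3, 0.05), abs(0.25 - 0.2) / 0.2 * 100)
  expect_error(mape_thresholded(1, 2, 0), "threshold")
  expect_error(mape_thresholded(c(1, 1), c(0.01, 0.02), 0.05), "no samples")
})

test_that("permutation importance isolates informative channels", {
  set.seed(9)
  n <- 600
  ds <- tibble::tibble(
    participant_id = rep(c("a", "b", "c"), each = n / 3),
    signal = rnorm(n), noise = rnorm(n), flat = rep(1, n)
  )
  ds$target <- ds$signal
  fit <- loso_cv(ds, gbdt_config(seed = 1), channels = c("signal", "noise", "flat"))
  imp <- permutation_importance(fit, ds, repeats = 5, seed = 2)
  expect_equal(imp$channel[1], "signal")
  # shuffling the only informative channel destroys essentially all accuracy
  base_r2 <- mean(tidy(fit)$r2)
  expect_gt(imp$delta_r2[imp$channel == "signal"], 0.8 * base_r2)
  # an all-constant channel has zero importance
  expect_lt(abs(imp$delta_r2[imp$channel == "flat"]), 1e-6)
  expect_equal(sort(imp$rank), 1:3)
})

test_that("a redundant informative channel can look unimportant", {
  # Two noisy copies of the same signal: the ensemble leans on whichever
  # copy it prefers, so the other shows a small delta-r2 even though it
  # predicts the target well on its own. This is why permutation importance
  # under-credits signals that are highly correlated with other inputs.
  set.seed(10)
  n <- 600
  common <- rnorm(n)
  ds <- tibble::tibble(
    participant_id = rep(c("a", "b", "c"), each = n / 3),
    s1 = common + rnorm(n, 0, 0.3),
    s2 = common + rnorm(n, 0, 0.3),
    target = common
  )
  fit <- loso_cv(ds, gbdt_config(seed = 3), channels = c("s1", "s2"))
  imp <- permutation_importance(fit, ds, repeats = 5, seed = 4)
  base_r2 <- mean(tidy(fit)$r2)
  expect_lt(min(imp$delta_r2), 0.4 * base_r2)
  # ... although the under-credited copy alone is a strong predictor
  spare <- imp$channel[which.min(imp$delta_r2)]
  solo <- loso_cv(ds, gbdt_config(seed = 3), channels = spare)
  expect_gt(mean(tidy(solo)$r2), 0.8)
})

test_that("moment-to-compression and BW conversions match worked arithmetic", {
  expect_equal(moment_to_compression(7, 0.07), 100)
  b1 <- force_to_bw(3400, 79)
  expect_equal(b1$bw, 3400 / (79 * 9.81), tolerance = 1e-12)
  expect_equal(b1$bw_rounded, 4.4)
  b2 <- force_to_bw(241, 79)
  expect_equal(b2$bw_rounded, 0.3)
  expect_error(moment_to_compression(7, 0), "moment_arm")
  expect_error(force_to_bw(100, -1), "body_mass")
})

test_that("signed-rank test: exact extremes and the degenerate case", {
  # all 10 differences positive (and distinct) -> two-sided exact p = 2 / 2^10
  a <- 1:10 + (1:10) / 20; b <- as.numeric(1:10)
  expect_equal(wilcoxon_paired(a, b), 2 / 1024, tolerance = 1e-12)
  # signed ranks balanced around the null median -> p = 1
  d <- c(1, -2, 3, -4, -5, 6, -7, 8)
  expect_equal(wilcoxon_paired(d, rep(0, 8)), 1, tolerance = 1e-12)
  expect_error(wilcoxon_paired(1:5, 1:5), "zero")
  expect_error(wilcoxon_paired(1:4, 1:5), "equal length")
})
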