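# Gradient-boosted estimator and leave-one-subject-out cross-validation.

make_xy <- function(n = 1500, p = 5, seed = 2) {
  set.seed(seed)
  X <- tibble::as_tibble(setNames(as.data.frame(matrix(rnorm(n * p), n, p)),
                                  paste0("x", seq_len(p))))
  X
}

test_that("a constant target is fit exactly and fits are deterministic", {
  X <- make_xy()
  m <- gbdt_fit(X, rep(4.2, nrow(X)), gbdt_config(seed = 1),
                channels = names(X))
  # predictions are float32; exact up to single precision
  expect_lt(max(abs(gbdt_predict(m, X) - 4.2)), 1e-6)

  y <- X$x1 * 2 + X$x2
  m1 <- gbdt_fit(X, y, gbdt_config(seed = 3), channels = names(X))
  m2 <- gbdt_fit(X, y, gbdt_config(seed = 3), channels = names(X))
  expect_identical(gbdt_predict(m1, X), gbdt_predict(m2, X))
})

test_that("the ensemble recovers a target equal to one input channel", {
  X <- make_xy()
  y <- X$x3
  m <- gbdt_fit(X, y, gbdt_config(), channels = names(X))
  p <- gbdt_predict(m, X)
  r2 <- 1 - sum((y - p)^2) / sum((y - mean(y))^2)
  expect_gt(r2, 0.99)
})

test_that("prediction is stateless: permutation and duplication behave", {
  X <- make_xy(n = 400)
  y <- X$x1 + 0.2 * X$x2^2
  m <- gbdt_fit(X, y, gbdt_config(), channels = names(X))
  p <- gbdt_predict(m, X)
  idx <- sample(nrow(X))
  expect_equal(gbdt_predict(m, X[idx, ]), p[idx], tolerance = 1e-12)
  expect_equal(gbdt_predict(m, X[c(7, 7), ]), rep(p[7], 2), tolerance = 1e-12)
  expect_error(gbdt_predict(m, X[, 1:3]), "schema mismatch")
})

test_that("an all-constant channel changes no prediction", {
  X <- make_xy(n = 800)
  y <- X$x1 * 3 + rnorm(800, 0, 0.05)
  m1 <- gbdt_fit(X, y, gbdt_config(seed = 5), channels = names(X))
  X2 <- X; X2$const <- 7
  m2 <- gbdt_fit(X2, y, gbdt_config(seed = 5), channels = names(X2))
  expect_equal(gbdt_predict(m2, X2), gbdt_predict(m1, X), tolerance = 1e-12)
})

test_that("errors: empty training set and non-finite targets", {
  X <- make_xy(n = 10)
  expect_error(gbdt_fit(X[0, ], numeric(0), channels = names(X)), "empty")
  expect_error(gbdt_fit(X, c(rep(1, 9), NaN), channels = names(X)),
               "non-finite")
  expect_error(gbdt_config(n_trees = 0), "n_trees")
})

test_that("LOSO folds partition the data and never see the held-out subject", {
  ds <- micro_dataset()
  fit <- loso_cv(subset_dataset(ds, c("trunk", "insole")), gbdt_config(seed = 1))
  expect_equal(length(fit$folds), 3)
  expect_equal(nrow(fit$predictions), nrow(ds))
  # each sample predicted exactly once, folds disjoint by participant
  by_fold <- split(fit$predictions$participant_id, fit$predictions$fold)
  expect_true(all(vapply(by_fold, function(x) length(unique(x)) == 1, logical(1))))
  expect_setequal(unique(fit$predictions$participant_id),
                  unique(ds$participant_id))
  expect_error(loso_cv(ds[ds$participant_id == "p01", ]), "at least 2")
})

test_that("a leaked target channel yields near-perfect held-out accuracy", {
  ds <- subset_dataset(micro_dataset(), "trunk")
  leaked <- ds
  leaked$eul_trunk_x <- leaked$target # overwrite a channel with the answer
  fit <- loso_cv(leaked, gbdt_config(seed = 2))
  expect_gt(mean(tidy(fit)$r2), 0.99)
})

test_that("pure-noise inputs have no held-out predictive power", {
  ds <- subset_dataset(micro_dataset(), "trunk")
  r2s <- vapply(1:3, function(s) {
    noisy <- ds
    set.seed(100 + s)
    for (ch in c("eul_trunk_z", "eul_trunk_x", "eul_trunk_y")) {
      noisy[[ch]] <- rnorm(nrow(noisy))
    }
    mean(tidy(loso_cv(noisy, gbdt_config(seed = s)))$r2)
  }, numeric(1))
  expect_lt(mean(r2s), 0.05)
})
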