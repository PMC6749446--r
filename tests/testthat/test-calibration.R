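test_that("fold plans are balanced, complete and deterministic", {
  plan <- make_fold_plan(21, 5, 10, seed = 1)
  sizes <- t(apply(plan$assignments, 1, function(r) sort(tabulate(r, 5),
                                                         decreasing = TRUE)))
  for (r in 1:10) expect_identical(sizes[r, ], c(5L, 4L, 4L, 4L, 4L))
  expect_identical(plan$assignments,
                   make_fold_plan(21, 5, 10, seed = 1)$assignments)
  # repeats are (with overwhelming probability) distinct permutations
  keys <- apply(plan$assignments, 1, paste, collapse = "")
  expect_identical(anyDuplicated(keys), 0L)
  expect_error(make_fold_plan(4, 5), "n >= k")
  expect_error(make_fold_plan(10, 1), "k must be")
})

test_that("cv_fit is exact in the noiseless linear case", {
  set.seed(2)
  metric <- runif(21, 50, 300)
  mass <- 3 * metric
  plan <- make_fold_plan(21, 5, 10, seed = 3)
  fit <- cv_fit(metric, mass, plan)
  expect_equal(fit$r2, 1.0)
  expect_equal(fit$rmse_g, 0, tolerance = 1e-9)
  expect_equal(fit$rmse_direct_g, 0, tolerance = 1e-9)
  expect_equal(fit$slope, 3.0)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$fitted_mass_g, mass, tolerance = 1e-9)
})

test_that("cv_fit finds no signal in permuted data", {
  # out-of-fold predictions carry a small systematic anticorrelation with
  # the held-out responses (training-fold means exclude them), so the
  # null r2 is slightly above the naive 1/n but stays far from signal
  r2s <- vapply(1:40, function(s) {
    set.seed(s)
    metric <- runif(100, 50, 300)
    mass <- sample(2 * metric)        # permuted independently of metric
    plan <- make_fold_plan(100, 5, 2, seed = s)
    cv_fit(metric, mass, plan)$r2
  }, 0)
  expect_lt(median(r2s), 0.1)
  expect_lt(mean(r2s), 0.15)
  expect_lt(max(r2s), 0.5)
})

test_that("cv_fit validates its inputs", {
  plan <- make_fold_plan(10, 5, 2, seed = 1)
  expect_error(cv_fit(rep(1, 10), runif(10), plan), "zero variance")
  expect_error(cv_fit(runif(9), runif(10), plan), "differ in length")
  expect_error(cv_fit(runif(8), runif(8), plan), "different n")
})

test_that("out-of-fold discipline: own mass never leaks into own prediction", {
  set.seed(4)
  metric <- runif(20, 50, 300)
  mass <- 1.5 * metric + rnorm(20, 0, 10)
  plan <- make_fold_plan(20, 5, 1, seed = 5)
  base <- cv_fit(metric, mass, plan)
  mutated <- mass
  mutated[7] <- mutated[7] + 500
  changed <- cv_fit(metric, mutated, plan)
  expect_equal(changed$fitted_mass_g[7], base$fitted_mass_g[7])
  expect_false(isTRUE(all.equal(changed$fitted_mass_g[-7],
                                base$fitted_mass_g[-7])))
})

test_that("repeating CV does not inflate the variance of fitted values", {
  set.seed(6)
  metric <- runif(21, 50, 300)
  mass <- 2 * metric + rnorm(21, 0, 20)
  spread <- function(repeats) {
    fits <- vapply(1:25, function(s)
      cv_fit(metric, mass, make_fold_plan(21, 5, repeats,
                                          seed = s))$fitted_mass_g,
      numeric(21))
    mean(apply(fits, 1, sd))
  }
  expect_lte(spread(10), spread(1))
})

test_that("volume correction inverts an exact multiplicative bias", {
  set.seed(7)
  ref <- runif(21, 60, 280)
  sensor <- 1.2 * ref
  plan <- make_fold_plan(21, 5, 10, seed = 8)
  corr <- fit_volume_correction(sensor, ref, plan)
  expect_equal(corr$slope, 1 / 1.2)
  expect_equal(corr$intercept, 0, tolerance = 1e-9)
  expect_equal(corr$corrected_volumes, ref, tolerance = 1e-9)
  expect_equal(apply_correction(corr, 120), 100)
  ident <- fit_volume_correction(ref, ref, plan)
  expect_equal(apply_correction(ident, ref), ref, tolerance = 1e-9)
  # full-data fit matches reference mean exactly (least squares with
  # intercept passes through the means)
  fitted_full <- corr$slope * sensor + corr$intercept
  expect_equal(mean(fitted_full), mean(ref), tolerance = 1e-9)
})

test_that("correction fitted on one dataset transfers to a second", {
  set.seed(9)
  ref1 <- runif(21, 60, 280)
  ref2 <- runif(21, 60, 280)
  sensor1 <- apply_sensor_bias(ref1, 1.212, noise_sd_cm3 = 6, seed = 10)
  sensor2 <- apply_sensor_bias(ref2, 1.212, noise_sd_cm3 = 6, seed = 11)
  plan <- make_fold_plan(21, 5, 10, seed = 12)
  corr <- fit_volume_correction(sensor1, ref1, plan)
  corrected2 <- apply_correction(corr, sensor2)
  expect_lt(abs(mean(corrected2) - mean(ref2)) / mean(ref2), 0.05)
})

test_that("yield diagnostics follow the regression convention", {
  set.seed(13)
  actual <- runif(30, 100, 400)
  exact <- evaluate_yield(actual, actual)
  expect_equal(exact$r2, 1.0)
  expect_equal(exact$rmse_g, 0, tolerance = 1e-9)
  offset <- evaluate_yield(actual + 50, actual)
  expect_equal(offset$r2, 1.0)
  expect_equal(offset$rmse_g, 0, tolerance = 1e-9)
  indep <- evaluate_yield(rnorm(1000), rnorm(1000))
  expect_lt(indep$r2, 0.01)
  expect_error(evaluate_yield(runif(5), rep(2, 5)), "zero variance")
  expect_error(evaluate_yield(runif(2), runif(2)), "at least 3")
})
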