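#' Repeated k-fold partition plan
#'
#' Balanced fold assignments (fold sizes differ by at most one) for each
#' repeat, deterministic in the seed.
#'
#' @param n number of samples (>= k).
#' @param k number of folds (default 5).
#' @param repeats number of repeated partitions (default 10).
#' @param seed integer seed.
#' @return Object of class `fold_plan` with an `assignments` matrix of
#'   dimension `repeats x n` holding fold indices in `1..k`.
#' @export
make_fold_plan <- function(n, k = 5L, repeats = 10L, seed = 1L) {
  n <- as.integer(n); k <- as.integer(k); repeats <- as.integer(repeats)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("need n >= k samples")
  if (repeats < 1) stop("repeats must be >= 1")
  assignments <- with_rng_seed(seed, {
    t(vapply(seq_len(repeats),
             function(r) sample(rep_len(seq_len(k), n)),
             integer(n)))
  })
  structure(list(k = k, repeats = repeats, n = n, seed = as.integer(seed),
                 assignments = assignments), class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan: n = %d, k = %d, repeats = %d, seed = %d>\n",
              x$n, x$k, x$repeats, x$seed))
  invisible(x)
}

# out-of-fold predictions of y from a univariate linear model in x,
# averaged over the plan's repeats
oof_predictions <- function(x, y, plan) {
  preds <- matrix(NA_real_, plan$repeats, plan$n)
  for (r in seq_len(plan$repeats)) {
    fold <- plan$assignments[r, ]
    for (f in seq_len(plan$k)) {
      test <- fold == f
      xt <- x[!test]; yt <- y[!test]
      if (stats::var(xt) <= 0)
        stop("zero-variance metric within a training fold")
      b <- stats::cov(xt, yt) / stats::var(xt)
      a <- mean(yt) - b * mean(xt)
      preds[r, test] <- a + b * x[test]
    }
  }
  colMeans(preds)
}

#' Cross-validated linear yield model
#'
#' Per repeat of the fold plan, each sample's mass is predicted by the
#' linear model `mass ~ metric` trained on the folds excluding it; the
#' per-sample fitted mass is the mean of these out-of-fold predictions
#' over repeats. The reported r-squared and RMSE come from the ordinary
#' least-squares regression of fitted mass on actual mass (`rmse_g` is
#' that regression's residual RMSE); the direct prediction error
#' `sqrt(mean((fitted - actual)^2))` is reported alongside as
#' `rmse_direct_g`. A full-data model (`slope`, `intercept`) is stored
#' for deployment on new metric values.
#'
#' @param metric per-sample area (cm^2) or volume (cm^3).
#' @param mass_g per-sample reference mass (g).
#' @param plan a [make_fold_plan()] for `length(metric)` samples.
#' @return Object of class `yield_model`.
#' @export
cv_fit <- function(metric, mass_g, plan) {
  stopifnot(inherits(plan, "fold_plan"))
  if (length(metric) != length(mass_g)) stop("metric and mass differ in length")
  if (length(metric) != plan$n) stop("plan was made for a different n")
  if (length(metric) < 3) stop("need at least 3 samples")
  if (stats::var(metric) <= 0) stop("metric has zero variance")
  fitted <- oof_predictions(metric, mass_g, plan)
  ev <- evaluate_yield(fitted, mass_g)
  full <- lm(mass_g ~ metric)
  structure(list(
    slope = unname(coef(full)[2]), intercept = unname(coef(full)[1]),
    fitted_mass_g = fitted, actual_mass_g = mass_g, metric = metric,
    r2 = ev$r2, rmse_g = ev$rmse_g,
    rmse_direct_g = sqrt(mean((fitted - mass_g)^2)),
    k = plan$k, repeats = plan$repeats, seed = plan$seed),
    class = "yield_model")
}

#' @export
print.yield_model <- function(x, ...) {
  cat(sprintf(
    "<yield_model: mass = %.4f * metric + %.3f; r2 = %.3f, RMSE = %.3f g (n = %d)>\n",
    x$slope, x$intercept, x$r2, x$rmse_g, length(x$fitted_mass_g)))
  invisible(x)
}

#' Cross-validated sensor volume correction
#'
#' Fits the linear map `reference ~ sensor` with out-of-fold prediction
#' per the fold plan; `corrected_volumes` are the per-sample out-of-fold
#' predictions (averaged over repeats). The stored full-data model is
#' what [apply_correction()] uses on other datasets.
#'
#' @param sensor_volumes_cm3 sensor-estimated volumes.
#' @param reference_volumes_cm3 reference (displacement) volumes.
#' @param plan a [make_fold_plan()].
#' @return Object of class `volume_correction` with `slope`, `intercept`
#'   and `corrected_volumes`.
#' @export
fit_volume_correction <- function(sensor_volumes_cm3, reference_volumes_cm3,
                                  plan) {
  stopifnot(inherits(plan, "fold_plan"))
  if (length(sensor_volumes_cm3) != length(reference_volumes_cm3))
    stop("sensor and reference volumes differ in length")
  if (length(sensor_volumes_cm3) < 3) stop("need at least 3 samples")
  if (any(sensor_volumes_cm3 < 0) || any(reference_volumes_cm3 < 0))
    stop("volumes must be non-negative")
  if (stats::var(sensor_volumes_cm3) <= 0)
    stop("sensor volumes have zero variance")
  corrected <- oof_predictions(sensor_volumes_cm3, reference_volumes_cm3,
                               plan)
  full <- lm(reference_volumes_cm3 ~ sensor_volumes_cm3)
  structure(list(slope = unname(coef(full)[2]),
                 intercept = unname(coef(full)[1]),
                 corrected_volumes = corrected,
                 sensor_volumes = sensor_volumes_cm3,
                 reference_volumes = reference_volumes_cm3),
            class = "volume_correction")
}

#' @export
print.volume_correction <- function(x, ...) {
  cat(sprintf("<volume_correction: ref = %.4f * sensor + %.3f>\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Apply a fitted volume correction to new sensor volumes
#'
#' @param model a [fit_volume_correction()] result.
#' @param sensor_volumes_cm3 volumes to correct.
#' @return Corrected volumes; negatives are clamped to 0 with a warning.
#' @export
apply_correction <- function(model, sensor_volumes_cm3) {
  stopifnot(inherits(model, "volume_correction"))
  out <- model$slope * sensor_volumes_cm3 + model$intercept
  if (any(out < 0)) {
    warning("negative corrected volume clamped to 0")
    out[out < 0] <- 0
  }
  out
}

#' Yield-estimation diagnostics
#'
#' Ordinary least-squares regression of estimated on actual mass; the
#' returned r-squared is that regression's coefficient of determination
#' and `rmse_g` the RMSE of its residuals, in grams. A constant offset
#' between estimated and actual is absorbed by the regression (the
#' diagnostic measures agreement up to a linear map).
#'
#' @param estimated_mass_g,actual_mass_g congruent vectors (n >= 3).
#' @return List with `r2` and `rmse_g`.
#' @export
evaluate_yield <- function(estimated_mass_g, actual_mass_g) {
  if (length(estimated_mass_g) != length(actual_mass_g))
    stop("estimated and actual differ in length")
  if (length(actual_mass_g) < 3) stop("need at least 3 samples")
  if (stats::var(actual_mass_g) <= 0) stop("actual mass has zero variance")
  fit <- lm(estimated_mass_g ~ actual_mass_g)
  rss <- sum(residuals(fit)^2)
  tss <- sum((estimated_mass_g - mean(estimated_mass_g))^2)
  list(r2 = if (tss > 0) 1 - rss / tss else 1.0,
       rmse_g = sqrt(mean(residuals(fit)^2)))
}
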