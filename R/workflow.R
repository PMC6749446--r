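#' Experiment configuration
#'
#' Describes one synthetic experiment: the measurement level (laboratory
#' bunch, in-field bunch, in-field vine with east/west sides), the canopy
#' treatment, the sensing branch, and generator/analysis parameters.
#'
#' @param experiment one of `"exp1_lab_bunch"`, `"exp2_field_bunch"`,
#'   `"exp3_field_vine"`.
#' @param treatment `"none"` (required for exp1), `"FC"` or `"LR"`.
#' @param branch `"rgb"` (image segmentation + area) or `"rgbd"`
#'   (mesh/point-cloud volume).
#' @param n_samples bunches (exp1/2, default 21) or vines (exp3,
#'   default 31).
#' @param seed master seed; all stage seeds derive from it.
#' @param generator,analysis named lists overriding the defaults listed
#'   below.
#' @return Object of class `experiment_config`.
#'
#' @details Generator defaults: berry radius 0.6 cm, 30-90 berries per
#' bunch in a 5.5 x 3.0 x 2.4 cm ellipsoid envelope (a conical bunch
#' slightly flattened along the camera axis), 8 px/cm imagery, 200
#' surface points per berry with 0.02 cm
#' sensor noise, density 1 g/cm^3, mass noise set for a mass-volume
#' r-squared of 0.971 at bunch level and 0.996 at vine level, FC leaf
#' cover 0.3. Analysis defaults: threshold quantile 0.002, 25% training
#' and 25% disjoint testing splits, 5-fold cross-validation repeated 10
#' times, sensor volume bias 1.212 with 4% multiplicative noise, alpha
#' grid 0.2-1.5 cm (step 0.1) for the point-cloud branch.
#' @export
experiment_config <- function(experiment = c("exp1_lab_bunch",
                                             "exp2_field_bunch",
                                             "exp3_field_vine"),
                              treatment = NULL,
                              branch = c("rgb", "rgbd"),
                              n_samples = NULL, seed = 1L,
                              generator = list(), analysis = list()) {
  experiment <- match.arg(experiment)
  branch <- match.arg(branch)
  if (is.null(treatment))
    treatment <- if (experiment == "exp1_lab_bunch") "none" else "LR"
  if (experiment == "exp1_lab_bunch" && treatment != "none")
    stop("exp1_lab_bunch requires treatment 'none'")
  if (experiment != "exp1_lab_bunch" && !(treatment %in% c("FC", "LR")))
    stop("field experiments require treatment 'FC' or 'LR'")
  if (is.null(n_samples))
    n_samples <- if (experiment == "exp3_field_vine") 31L else 21L
  n_samples <- as.integer(n_samples)
  if (n_samples < 5) stop("need at least 5 samples")
  gen <- utils::modifyList(list(
    berry_radius_cm = 0.6,
    n_berries_range = c(30L, 90L),
    envelope = c(5.5, 3.0, 2.4),
    pixels_per_cm = 8,
    points_per_berry = 200L,
    truth_resolution_cm = 0.05,
    sensor_noise_sd_cm = 0.02,
    n_canopy_points = if (experiment == "exp3_field_vine") 600L else 0L,
    density_g_per_cm3 = 1.0,
    target_r2 = if (experiment == "exp3_field_vine") 0.996 else 0.971,
    leaf_cover_fraction = if (treatment == "FC") 0.3 else 0), generator)
  ana <- utils::modifyList(list(
    quantile = 0.002,
    train_fraction = 0.25,
    k = 5L, repeats = 10L,
    alpha = NULL,                      # NULL: auto / tuned
    alpha_grid = seq(0.2, 1.5, by = 0.1),
    sensor_bias = 1.212,
    sensor_noise_frac = 0.04,
    colour_quantile = 0.01), analysis)
  structure(list(experiment = experiment, treatment = treatment,
                 branch = branch, n_samples = n_samples,
                 seed = as.integer(seed), generator = gen, analysis = ana),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config: %s / %s / %s, n = %d, seed = %d>\n",
              x$experiment, x$treatment, x$branch, x$n_samples, x$seed))
  invisible(x)
}

# disjoint training (threshold fitting) and testing (evaluation) index
# sets, each a `fraction` of the samples
split_train_test <- function(n, fraction, seed) {
  n_tr <- max(1L, round(fraction * n))
  n_te <- max(1L, round(fraction * n))
  with_rng_seed(seed, {
    idx <- sample.int(n)
    list(train = sort(idx[seq_len(n_tr)]),
         test = sort(idx[n_tr + seq_len(min(n_te, n - n_tr))]))
  })
}

derive_seeds <- function(seed, n) {
  with_rng_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Run a synthetic experiment end to end
#'
#' Generates the synthetic dataset for the configuration, runs the
#' configured branch (segmentation + calibrated area, or reconstruction /
#' alpha-complex volume with sensor-bias correction), and calibrates the
#' cross-validated yield model. For the vine-level experiment, per-side
#' measurements are combined into per-vine means before calibration. FC
#' runs should reuse the thresholds / colour box / alpha / volume
#' correction fitted on the matching LR run by passing that run's
#' `$artifacts`.
#'
#' @param config an [experiment_config()].
#' @param artifacts optional artifacts list from a previous (LR) run.
#' @return List of class `experiment_result` with elements `config`,
#'   `reference` (reference table), `metrics` (per-sample data frame),
#'   `segmentation` (mean F1/accuracy on the held-out test split; rgb
#'   branch only), `model` (the [cv_fit()] yield model), `artifacts`,
#'   and `summary`.
#' @export
run_experiment <- function(config, artifacts = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  gen <- config$generator
  ana <- config$analysis
  n <- config$n_samples
  two_sided <- config$experiment == "exp3_field_vine"
  seeds <- derive_seeds(config$seed, 6L + 4L * n)
  smat <- matrix(seeds[seq_len(4L * n)], n, 4)  # per-sample stage seeds
  occ <- occlusion_config(if (config$treatment == "FC") "FC" else "LR",
                          gen$leaf_cover_fraction)

  # --- synthesize ground truth ---------------------------------------
  n_berries <- with_rng_seed(seeds[4L * n + 1L],
    sample(seq(gen$n_berries_range[1], gen$n_berries_range[2]), n,
           replace = TRUE))
  clusters <- lapply(seq_len(n), function(i)
    generate_bunch_cluster(n_berries[i], gen$berry_radius_cm,
                           scaled_envelope(n_berries[i], gen$envelope,
                                           mean(gen$n_berries_range)),
                           seed = smat[i, 1]))
  true_vol <- vapply(clusters, cluster_volume, 0,
                     resolution_cm = gen$truth_resolution_cm)
  noise_sd <- noise_sd_for_target_r2(true_vol, gen$density_g_per_cm3,
                                     gen$target_r2)
  reference <- generate_reference_table(true_vol, gen$density_g_per_cm3,
                                        noise_sd, seed = seeds[4L * n + 2L])
  plan <- make_fold_plan(n, ana$k, ana$repeats, seed = seeds[4L * n + 3L])
  split <- split_train_test(n, ana$train_fraction, seeds[4L * n + 4L])

  segmentation <- NULL
  out_artifacts <- list()

  if (config$branch == "rgb") {
    sides <- if (two_sided) c("east", "west") else "single"
    scenes <- lapply(seq_len(n), function(i) {
      lapply(seq_along(sides), function(s)
        render_bunch_image(clusters[[i]], occ, gen$pixels_per_cm,
                           seed = smat[i, s + 1L],
                           density_g_per_cm3 = gen$density_g_per_cm3))
    })
    thresholds <- artifacts$thresholds
    if (is.null(thresholds)) {
      training <- lapply(split$train, function(i)
        list(image = scenes[[i]][[1]]$scene,
             mask = scenes[[i]][[1]]$truth$true_mask))
      thresholds <- fit_thresholds(training, ana$quantile)
    }
    calib <- calibrate_scale(scenes[[1]][[1]]$scene$ruler_px,
                             scenes[[1]][[1]]$scene$ruler_cm)
    seg <- lapply(scenes, function(sc) lapply(sc, function(s)
      segment_scene(s$scene, thresholds, calib)))
    areas <- vapply(seg, function(sd2) {
      a <- vapply(sd2, function(s) s$area_cm2, 0)
      if (length(a) == 2) tbav(a[1], a[2]) else a[1]
    }, 0)
    evals <- lapply(split$test, function(i)
      evaluate_segmentation(seg[[i]][[1]]$mask,
                            scenes[[i]][[1]]$truth$true_mask))
    segmentation <- list(
      f1 = mean(vapply(evals, function(e) e$f1, 0)),
      accuracy = mean(vapply(evals, function(e) e$accuracy, 0)),
      n_test = length(evals))
    metric <- areas
    metrics <- data.frame(sample_id = reference$sample_id,
                          side = if (two_sided) "combined" else "single",
                          area_cm2 = areas)
    out_artifacts$thresholds <- thresholds
  } else {
    sides <- if (two_sided) c("east", "west") else "single"
    clouds <- lapply(seq_len(n), function(i) {
      lapply(seq_along(sides), function(s)
        sample_bunch_point_cloud(
          clusters[[i]], gen$points_per_berry,
          sensor_noise_sd_cm = gen$sensor_noise_sd_cm,
          occlusion = occ, n_canopy_points = gen$n_canopy_points,
          seed = smat[i, s + 1L],
          density_g_per_cm3 = gen$density_g_per_cm3)$cloud)
    })
    if (two_sided) {
      # point-cloud branch: colour filtering then alpha-complex volume
      colour_box <- artifacts$colour_box
      if (is.null(colour_box)) {
        berry_cols <- do.call(rbind, lapply(split$train, function(i) {
          cl <- clouds[[i]][[1]]
          cl$colours[cl$label == "berry", , drop = FALSE]
        }))
        colour_box <- fit_colour_box(berry_cols, ana$colour_quantile)
      }
      filtered <- lapply(clouds, function(cl) lapply(cl, function(x)
        filter_points_by_colour(x, colour_box$rgb_lo, colour_box$rgb_hi)))
      alpha <- artifacts$alpha %||% ana$alpha
      tuning <- NULL
      if (is.null(alpha)) {
        tuning <- tune_alpha(lapply(split$train,
                                    function(i) filtered[[i]][[1]]),
                             reference$volume_ml[split$train],
                             ana$alpha_grid)
        alpha <- tuning$selected_alpha
      }
      side_vols <- vapply(filtered, function(cl)
        vapply(cl, function(x) alpha_complex_volume(x, alpha)$volume_cm3, 0),
        numeric(length(sides)))
      est_vol <- tbvv(side_vols[1, ], side_vols[2, ])
      out_artifacts$colour_box <- colour_box
      out_artifacts$alpha <- alpha
      out_artifacts$tuning <- tuning
    } else {
      # mesh branch: watertight reconstruction then enclosed volume
      alpha <- artifacts$alpha %||% ana$alpha %||% gen$berry_radius_cm
      est_vol <- vapply(seq_len(n), function(i) {
        mesh <- tryCatch(reconstruct_watertight(clouds[[i]][[1]], alpha),
                         error = function(e)
                           reconstruct_watertight(clouds[[i]][[1]], NULL))
        mesh_volume(mesh)
      }, 0)
      out_artifacts$alpha <- alpha
    }
    sensor_vol <- apply_sensor_bias(
      est_vol, ana$sensor_bias,
      noise_sd_cm3 = ana$sensor_noise_frac * mean(est_vol),
      seed = seeds[4L * n + 5L])
    correction <- artifacts$correction
    if (is.null(correction)) {
      correction <- fit_volume_correction(sensor_vol, reference$volume_ml,
                                          plan)
      corrected <- correction$corrected_volumes
    } else {
      corrected <- apply_correction(correction, sensor_vol)
    }
    out_artifacts$correction <- correction
    metric <- corrected
    metrics <- data.frame(sample_id = reference$sample_id,
                          side = if (two_sided) "combined" else "single",
                          sensor_volume_cm3 = sensor_vol,
                          corrected_volume_cm3 = corrected)
  }

  model <- cv_fit(metric, reference$mass_g, plan)
  metrics$fitted_mass_g <- model$fitted_mass_g
  metrics$actual_mass_g <- reference$mass_g
  res <- list(
    config = config, reference = reference, metrics = metrics,
    segmentation = segmentation, model = model, artifacts = out_artifacts,
    summary = list(r2 = model$r2, rmse_g = model$rmse_g,
                   slope = model$slope, intercept = model$intercept,
                   k = plan$k, repeats = plan$repeats,
                   seed = config$seed))
  class(res) <- "experiment_result"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result: %s / %s / %s>\n",
              x$config$experiment, x$config$treatment, x$config$branch))
  cat(sprintf("  yield model: r2 = %.3f, RMSE = %.2f g\n",
              x$summary$r2, x$summary$rmse_g))
  if (!is.null(x$segmentation))
    cat(sprintf("  segmentation: F1 = %.3f, accuracy = %.3f (test n = %d)\n",
                x$segmentation$f1, x$segmentation$accuracy,
                x$segmentation$n_test))
  invisible(x)
}

#' Write an experiment result bundle to a directory
#'
#' Writes the per-sample metrics CSV, the model summary JSON, the
#' reference table CSV, a parameter sidecar YAML, and (for a tuned
#' point-cloud run) the alpha tuning curve CSV and plot.
#'
#' @param result an `experiment_result`.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_result_bundle <- function(result, dir) {
  stopifnot(inherits(result, "experiment_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$metrics, file.path(dir, "metrics.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(result$reference),
            file.path(dir, "reference.csv"), row.names = FALSE)
  jsonlite::write_json(result$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_sidecar_yaml(list(
    experiment = result$config$experiment,
    treatment = result$config$treatment,
    branch = result$config$branch,
    n_samples = result$config$n_samples,
    seed = result$config$seed,
    generator = result$config$generator,
    analysis = result$config$analysis[
      !vapply(result$config$analysis, is.null, TRUE)]),
    file.path(dir, "config.yaml"))
  if (!is.null(result$artifacts$thresholds))
    write_thresholds_yaml(result$artifacts$thresholds,
                          file.path(dir, "thresholds.yaml"))
  tuning <- result$artifacts$tuning
  if (!is.null(tuning)) {
    write.csv(tuning$curve, file.path(dir, "alpha_tuning.csv"),
              row.names = FALSE)
    grDevices::png(file.path(dir, "alpha_tuning.png"), width = 720,
                   height = 480)
    plot(tuning)
    dev.off()
  }
  invisible(dir)
}
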