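test_that("berry clusters are deterministic, bounded and connected", {
  a <- generate_bunch_cluster(15, 0.6, seed = 7)
  b <- generate_bunch_cluster(15, 0.6, seed = 7)
  expect_identical(a$centers, b$centers)
  expect_false(identical(a$centers,
                         generate_bunch_cluster(15, 0.6, seed = 8)$centers))
  # envelope containment
  env <- a$envelope
  expect_true(all(rowSums(sweep(a$centers, 2, env, "/")^2) <= 1 + 1e-12))
  # minimum separation and overlap-connectivity graph
  d <- as.matrix(dist(a$centers))
  diag(d) <- Inf
  expect_gte(min(d), 1.25 * 0.6)
  adj <- d < 2 * 0.6
  reach <- rep(FALSE, 15); reach[1] <- TRUE
  for (k in 1:15) reach <- reach | (adj %*% reach > 0)
  expect_true(all(reach))
})

test_that("degenerate cluster sizes behave as documented", {
  empty <- generate_bunch_cluster(0, 0.6, seed = 1)
  expect_identical(nrow(empty$centers), 0L)
  expect_identical(cluster_volume(empty), 0)
  one <- generate_bunch_cluster(1, 1.0, seed = 1)
  expect_equal(cluster_volume(one), 4 * pi / 3, tolerance = 1e-12)
  expect_error(generate_bunch_cluster(400, 0.6, envelope = c(1, 1, 1),
                                      seed = 1, max_attempts = 50L),
               "over-packed")
})

test_that("generator volume agrees with the independent voxel oracle", {
  cl <- generate_bunch_cluster(50, 0.6, envelope = c(3.5, 2.5, 2.5),
                               seed = 13)
  gen <- cluster_volume(cl, resolution_cm = 0.01)
  oracle <- voxel_union_oracle(cl$centers, cl$radius, res = 0.02)
  expect_lt(abs(gen - oracle) / oracle, 0.01)
})

test_that("rendered scenes carry exact pixel-count ground truth", {
  empty <- generate_bunch_cluster(0, 0.6, seed = 1)
  sc0 <- render_bunch_image(empty, seed = 2)
  expect_identical(sc0$truth$true_area_cm2, 0)
  cl <- generate_bunch_cluster(12, 0.6, seed = 3)
  lr <- render_bunch_image(cl, occlusion_config("LR"), pixels_per_cm = 10,
                           seed = 4)
  # no occlusion: mask area equals the projected disk-union pixel count
  expect_identical(lr$truth$true_area_cm2, lr$truth$unoccluded_area_cm2)
  expect_identical(sum(lr$truth$true_mask) / 100, lr$truth$true_area_cm2)
  # scale metadata round-trips through calibration
  calib <- calibrate_scale(lr$scene$ruler_px, lr$scene$ruler_cm)
  expect_identical(calib$pixels_per_cm, 10)
})

test_that("occlusion hides close to the requested fraction and is monotone", {
  cl <- generate_bunch_cluster(15, 0.6, seed = 5)
  fc <- render_bunch_image(cl, occlusion_config("FC", 0.4), seed = 6)
  target <- fc$truth$realized_cover
  visible_frac <- fc$truth$true_area_cm2 / fc$truth$unoccluded_area_cm2
  expect_lt(abs((1 - visible_frac) - target), 0.15)
  covers <- c(0, 0.1, 0.2, 0.3, 0.45)
  areas <- vapply(covers, function(cv) {
    occ <- occlusion_config(if (cv > 0) "FC" else "LR", cv)
    render_bunch_image(cl, occ, seed = 6)$truth$true_area_cm2
  }, 0)
  expect_true(all(diff(areas) <= 1e-12))
})

test_that("point clouds are deterministic with exact surface geometry", {
  cl <- generate_bunch_cluster(1, 0.8, seed = 9)
  pc <- sample_bunch_point_cloud(cl, 200, sensor_noise_sd_cm = 0, seed = 10)
  d <- sqrt(rowSums(sweep(pc$cloud$points, 2, cl$centers[1, ])^2))
  expect_equal(max(abs(d - 0.8)), 0, tolerance = 1e-12)
  again <- sample_bunch_point_cloud(cl, 200, sensor_noise_sd_cm = 0,
                                    seed = 10)
  expect_identical(pc$cloud$points, again$cloud$points)
  expect_identical(pc$cloud$colours, again$cloud$colours)
})

test_that("reference tables follow the linear mass-volume model", {
  tab0 <- generate_reference_table(c(100, 200, 300), 1.0, 0, seed = 1)
  expect_identical(tab0$mass_g, c(100, 200, 300))
  tab <- generate_reference_table(c(100, 200, 300), 1.08, 0, seed = 1)
  expect_equal(tab$mass_g / tab$volume_ml, rep(1.08, 3))
  expect_identical(anyDuplicated(tab$sample_id), 0L)
})

test_that("noise tuned for a target r2 reproduces it over replicates", {
  set.seed(20)
  vols <- runif(21, 50, 300)
  sd_g <- noise_sd_for_target_r2(vols, 1.0, target_r2 = 0.97)
  r2s <- vapply(1:200, function(s) {
    tab <- generate_reference_table(vols, 1.0, sd_g, seed = s)
    summary(lm(mass_g ~ volume_ml, tab))$r.squared
  }, 0)
  # the variance identity holds up to the O(1/n) small-sample bias of r2
  expect_lt(abs(mean(r2s) - 0.97), 0.01)
  # and the target sits well inside the replicate spread
  expect_gt(0.97, mean(r2s) - 3 * sd(r2s))
  expect_lt(0.97, mean(r2s) + 3 * sd(r2s))
})

test_that("sensor bias scales volumes and clamps negatives", {
  expect_identical(apply_sensor_bias(100, 1.2, 0), 120)
  expect_identical(apply_sensor_bias(c(3, 7), 1.0, 0), c(3, 7))
  expect_warning(out <- apply_sensor_bias(0.1, 1.212, noise_sd_cm3 = 50,
                                          seed = 3), "clamped")
  expect_gte(min(out), 0)
  # the default factor reproduces the documented overestimation ratio
  set.seed(30)
  vols <- runif(21, 50, 260)
  vols <- vols * 144.952 / mean(vols)     # mean matched to the reference
  biased <- apply_sensor_bias(vols, 1.212, 0)
  expect_equal(mean(biased), 175.672, tolerance = 5e-4)
})
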