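test_that("mesh_volume matches closed forms on primitive solids", {
  expect_equal(mesh_volume(make_box_mesh()), 1.0)
  expect_equal(mesh_volume(make_box_mesh(c(-1, -2, 0), c(1, 0, 3))), 12.0)
  expect_equal(mesh_volume(make_tetrahedron_mesh()), 1 / 6)
  ico <- make_icosphere(radius = 1, subdivisions = 3)
  expect_true(is_watertight(ico))
  expect_lt(abs(mesh_volume(ico) - 4 * pi / 3) / (4 * pi / 3), 0.01)
})

test_that("icosphere volume agrees with a Monte-Carlo point-in-mesh oracle", {
  ico <- make_icosphere(radius = 1, subdivisions = 2)
  mc <- mc_convex_mesh_volume(ico, n = 1e6, seed = 11)
  expect_lt(abs(mesh_volume(ico) - mc) / mc, 0.005)
})

test_that("mesh_volume is invariant under rigid motions", {
  cl <- generate_bunch_cluster(8, 0.6, seed = 3)
  mesh <- reconstruct_watertight(solid_cluster_cloud(cl, 120, 80, seed = 4))
  v0 <- mesh_volume(mesh)
  for (s in 1:5) {
    moved <- rigid_transform(mesh, random_rotation(s), c(10, -3, 5) * s)
    expect_lt(abs(mesh_volume(moved) - v0) / v0, 1e-9)
  }
})

test_that("mesh_volume rejects open meshes and names offending edges", {
  box <- make_box_mesh()
  open_box <- tri_mesh(box$vertices, box$faces[-1, , drop = FALSE])
  expect_false(is_watertight(open_box))
  expect_error(mesh_volume(open_box), "not watertight.*edge")
  expect_error(mesh_volume(tri_mesh(box$vertices,
                                    matrix(integer(0), 0, 3))),
               "not watertight")
})

test_that("crop_box keeps exactly the geometry inside the box", {
  set.seed(5)
  pts <- matrix(runif(3000), 1000, 3)
  cloud <- bunch_point_cloud(pts, matrix(128, 1000, 3))
  full <- crop_box(cloud, c(0, 0, 0), c(1, 1, 1))
  expect_identical(full$points, cloud$points)
  expect_warning(crop_box(cloud, c(2, 2, 2), c(3, 3, 3)), "no points")
  half <- crop_box(cloud, c(0, 0, 0), c(0.5, 1, 1))
  expect_identical(nrow(half$points), sum(pts[, 1] <= 0.5))
  box <- make_box_mesh()
  expect_equal(mesh_volume(crop_box(box, c(-1, -1, -1), c(2, 2, 2))), 1.0)
  emptied <- suppressWarnings(crop_box(box, c(5, 5, 5), c(6, 6, 6)))
  expect_identical(nrow(emptied$vertices), 0L)
})

test_that("alpha complex of a regular tetrahedron follows the circumradius rule", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  # circumradius sqrt(3/8) ~ 0.612 < 1 -> kept
  kept <- alpha_complex_volume(tet, 1)
  expect_equal(kept$volume_cm3, 1 / (6 * sqrt(2)), tolerance = 1e-12)
  expect_length(kept$kept_tetrahedra, 1)
  # alpha below the circumradius -> empty complex
  dropped <- alpha_complex_volume(tet, 0.5)
  expect_identical(dropped$volume_cm3, 0)
  expect_length(dropped$kept_tetrahedra, 0)
})

test_that("alpha-complex volume is monotone in alpha and capped by the hull", {
  cl <- generate_bunch_cluster(10, 0.6, seed = 21)
  pts <- solid_cluster_cloud(cl, 80, 40, seed = 22)
  tets <- delaunay_tets(pts)
  vols <- vapply(c(0.1, 0.2, 0.4, 0.8, 1.6, 1e6),
                 function(a) alpha_complex_volume(NULL, a, tets = tets)$volume_cm3,
                 0)
  expect_true(all(diff(vols) >= 0))
  hull <- convex_hull_volume(pts)
  expect_true(all(vols <= hull + 1e-9 * hull))
  expect_lt(abs(vols[length(vols)] - hull) / hull, 1e-9)
})

test_that("alpha complex at large alpha equals an independent convex hull", {
  set.seed(31)
  n <- 5000
  dirs <- matrix(rnorm(3 * n), n, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pts <- dirs * 2 * runif(n)^(1 / 3)  # sphere surface + interior, r = 2
  res <- alpha_complex_volume(pts, 1e6)
  hull <- convex_hull_volume(pts)
  expect_lt(abs(res$volume_cm3 - hull) / hull, 1e-9)
  # the hull of 5000 interior samples sits a few percent inside the ball
  expect_lt(abs(hull - 4 / 3 * pi * 8) / (4 / 3 * pi * 8), 0.10)
})

test_that("alpha_complex_volume handles degenerate inputs with a warning", {
  expect_warning(r1 <- alpha_complex_volume(matrix(runif(9), 3, 3), 1),
                 "fewer than 4")
  expect_identical(r1$volume_cm3, 0)
  flat <- cbind(matrix(runif(40), 20, 2), 0)
  expect_warning(r2 <- alpha_complex_volume(flat, 1), "coplanar")
  expect_identical(r2$volume_cm3, 0)
})

test_that("reconstruct_watertight closes an open hemisphere within tolerance", {
  set.seed(41)
  m <- 2000
  d <- matrix(rnorm(3 * m), m, 3)
  d <- d / sqrt(rowSums(d^2))
  d[, 3] <- abs(d[, 3])          # open back: spherical cap only
  mesh <- reconstruct_watertight(d)
  expect_true(is_watertight(mesh))
  half_ball <- 2 * pi / 3
  expect_lt(abs(mesh_volume(mesh) - half_ball) / half_ball, 0.15)
})

test_that("reconstruction recovers single-sphere volume across seeds", {
  errs <- vapply(1:10, function(s) {
    set.seed(s)
    d <- matrix(rnorm(3 * 800), 800, 3)
    d <- d / sqrt(rowSums(d^2)) * 1.3
    d <- d + matrix(rnorm(3 * 800, 0, 0.005), 800, 3)
    mesh <- reconstruct_watertight(d)
    abs(mesh_volume(mesh) - 4 / 3 * pi * 1.3^3) / (4 / 3 * pi * 1.3^3)
  }, 0)
  expect_lt(max(errs), 0.05)
})

test_that("reconstruct_watertight rejects degenerate input", {
  expect_error(reconstruct_watertight(rbind(c(0, 0, 0), c(1, 1, 1),
                                            c(2, 2, 2))),
               "reconstruction failed")
  flat <- cbind(matrix(runif(60), 30, 2), 0)
  expect_error(reconstruct_watertight(flat), "reconstruction failed")
})

test_that("idempotence: reconstructing a watertight cube preserves volume", {
  box <- make_box_mesh(c(0, 0, 0), c(2, 1, 1))
  mesh <- reconstruct_watertight(box$vertices)
  expect_true(is_watertight(mesh))
  expect_lt(abs(mesh_volume(mesh) - 2) / 2, 0.01)
})

test_that("colour filtering keeps exactly the in-box points", {
  cl <- generate_bunch_cluster(6, 0.6, seed = 51)
  pc <- sample_bunch_point_cloud(cl, 100, n_canopy_points = 300,
                                 seed = 52)$cloud
  all_kept <- filter_points_by_colour(pc, c(0, 0, 0), c(255, 255, 255))
  expect_identical(nrow(all_kept$points), nrow(pc$points))
  expect_message(none <- filter_points_by_colour(pc, c(0, 0, 0), c(5, 5, 5)),
                 "no points")
  expect_identical(nrow(none$points), 0L)
  box <- fit_colour_box(pc$colours[pc$label == "berry", ], 0.01)
  kept <- filter_points_by_colour(pc, box$rgb_lo, box$rgb_hi)
  recall <- sum(kept$label == "berry") / sum(pc$label == "berry")
  expect_gte(recall, 0.95)
  precision <- mean(kept$label == "berry")
  expect_gte(precision, 0.95)
})

test_that("decimation keeps every k-th point", {
  cl <- generate_bunch_cluster(4, 0.6, seed = 61)
  pc <- sample_bunch_point_cloud(cl, 100, seed = 62)$cloud
  d2 <- decimate_cloud(pc, 2L)
  expect_identical(nrow(d2$points), length(seq(1, nrow(pc$points), by = 2)))
  expect_identical(d2$points[2, ], pc$points[3, ])
})

test_that("tune_alpha recovers a grid member used to build the references", {
  set.seed(71)
  samples <- lapply(1:5, function(i)
    solid_cluster_cloud(generate_bunch_cluster(6 + 2 * i, 0.6, seed = 70 + i),
                        80, 40, seed = 170 + i))
  grid <- seq(0.2, 0.6, by = 0.1)
  a_star <- 0.4
  refs <- vapply(samples, function(p)
    alpha_complex_volume(p, a_star)$volume_cm3, 0)
  tuned <- tune_alpha(samples, refs, grid)
  expect_equal(tuned$selected_alpha, a_star)
  expect_equal(min(tuned$curve$rmse, na.rm = TRUE), 0, tolerance = 1e-6)
  # single-alpha grid selects that alpha
  single <- tune_alpha(samples, refs, 0.3)
  expect_equal(single$selected_alpha, 0.3)
  expect_identical(nrow(single$curve), 1L)
})

test_that("cropping a cloud never increases its alpha-complex volume", {
  cl <- generate_bunch_cluster(12, 0.6, seed = 81)
  pts <- solid_cluster_cloud(cl, 100, 60, seed = 82)
  full <- alpha_complex_volume(pts, 0.3)$volume_cm3
  cloud <- bunch_point_cloud(pts)
  cropped <- crop_box(cloud, apply(pts, 2, min),
                      apply(pts, 2, max) - c(1, 0, 0))
  part <- alpha_complex_volume(cropped$points, 0.3)$volume_cm3
  expect_lte(part, full + 1e-9)
})

test_that("tbvv averages the two sides and is symmetric", {
  expect_identical(tbvv(1000, 1400), 1200)
  expect_identical(tbvv(0, 0), 0)
  expect_identical(tbvv(123.4, 567.8), tbvv(567.8, 123.4))
  expect_error(tbvv(-1, 5), "non-negative")
})
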