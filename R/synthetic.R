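#' Default HSV colour model for synthetic scenes
#'
#' Hue/saturation/value bands (all on `[0, 1]`) for the four scene
#' classes: dark-purple berries, green canopy leaves, green background
#' and the neutral reference bar. Bands are wide enough to give textured
#' regions while keeping berry and foliage hues well separated, which is
#' the contrast the colour-threshold segmentation exploits.
#'
#' @return Named list of per-class `list(h, s, v)` ranges.
#' @export
default_colour_model <- function() {
  list(
    berry      = list(h = c(0.70, 0.83), s = c(0.35, 0.85), v = c(0.15, 0.55)),
    leaf       = list(h = c(0.24, 0.38), s = c(0.40, 0.90), v = c(0.20, 0.60)),
    background = list(h = c(0.22, 0.40), s = c(0.25, 0.70), v = c(0.35, 0.80)),
    ruler      = list(h = c(0.00, 0.00), s = c(0.00, 0.02), v = c(0.90, 0.98))
  )
}

#' Occlusion configuration for a canopy treatment
#'
#' `FC` (full canopy) hides a configurable fraction of bunch pixels or
#' points behind leaf-like occluders; `LR` (leaf removal) leaves the
#' bunch zone clear. The realized per-bunch cover fraction is drawn from
#' a Beta distribution centred on `leaf_cover_fraction` (concentration
#' 25), emulating bunch-to-bunch variation in canopy density.
#'
#' @param treatment `"FC"` or `"LR"`.
#' @param leaf_cover_fraction mean fraction of bunch pixels/points hidden;
#'   defaults to 0.3 for FC and 0 for LR. LR caps the fraction at 0.05.
#' @return Object of class `occlusion_config`.
#' @export
occlusion_config <- function(treatment = c("LR", "FC"),
                             leaf_cover_fraction = NULL) {
  treatment <- match.arg(treatment)
  if (is.null(leaf_cover_fraction))
    leaf_cover_fraction <- if (treatment == "FC") 0.3 else 0
  if (leaf_cover_fraction < 0 || leaf_cover_fraction >= 1)
    stop("leaf_cover_fraction must be in [0, 1)")
  if (treatment == "LR" && leaf_cover_fraction > 0.05)
    stop("LR treatment caps leaf_cover_fraction at 0.05")
  structure(list(treatment = treatment,
                 leaf_cover_fraction = leaf_cover_fraction),
            class = "occlusion_config")
}

# realized per-bunch cover fraction; monotone in the mean for a fixed
# uniform draw so increasing cover never reveals more of the bunch
realized_cover <- function(mean_cover, u, concentration = 25) {
  if (mean_cover <= 0) return(0)
  qbeta(u, mean_cover * concentration, (1 - mean_cover) * concentration)
}

#' Generate a synthetic berry cluster
#'
#' Berry centres are sampled uniformly inside an ellipsoidal bunch
#' envelope with rejection: each centre must keep a minimum separation of
#' `min_sep_factor * radius` from all others (berries may interpenetrate
#' but not coincide) and, after the first berry, must overlap at least
#' one earlier berry (centre distance below `2 * radius`) so the cluster
#' is connected.
#'
#' @param n_berries number of berries (>= 0).
#' @param berry_radius_cm berry radius in cm.
#' @param envelope length-3 ellipsoid semi-axes in cm.
#' @param min_sep_factor minimum centre separation in units of the
#'   radius; must be < 2 to allow connected overlap.
#' @param seed integer seed; the generator is deterministic in
#'   (parameters, seed).
#' @param max_attempts rejection budget per berry.
#' @return Object of class `berry_cluster` with `centers`, `radius`,
#'   `n_berries` and `envelope`.
#' @export
generate_bunch_cluster <- function(n_berries, berry_radius_cm = 0.6,
                                   envelope = c(5.5, 3.0, 2.4),
                                   min_sep_factor = 1.25, seed = 1L,
                                   max_attempts = 2000L) {
  if (n_berries < 0) stop("n_berries must be >= 0")
  stop_if_not_positive(berry_radius_cm, "berry_radius_cm")
  if (length(envelope) != 3 || any(envelope <= 0))
    stop("envelope must be 3 positive semi-axes")
  if (min_sep_factor >= 2)
    stop("min_sep_factor must be < 2 for a connected cluster")
  r <- berry_radius_cm
  centers <- with_rng_seed(seed, {
    cen <- matrix(0, n_berries, 3)
    placed <- 0L
    attempts <- 0L
    while (placed < n_berries) {
      attempts <- attempts + 1L
      if (attempts > max_attempts * max(1L, n_berries))
        stop("berry placement failed: envelope over-packed for ",
             n_berries, " berries of radius ", r)
      p <- runif(3, -1, 1)
      if (sum(p^2) > 1) next
      p <- p * envelope
      if (placed > 0L) {
        d <- sqrt(colSums((t(cen[seq_len(placed), , drop = FALSE]) - p)^2))
        if (min(d) < min_sep_factor * r) next
        if (min(d) >= 2 * r) next  # must attach to the cluster
      }
      placed <- placed + 1L
      cen[placed, ] <- p
    }
    cen
  })
  structure(list(centers = centers, radius = r,
                 n_berries = as.integer(n_berries), envelope = envelope,
                 seed = as.integer(seed)),
            class = "berry_cluster")
}

#' Bunch envelope scaled to the berry count
#'
#' Real bunches grow in overall size with berry number at roughly
#' constant packing density; this scales a reference envelope by
#' `(n_berries / n_ref)^(1/3)` so that bunches of different sizes remain
#' geometrically similar (and projected area keeps tracking volume).
#'
#' @param n_berries berry count of the bunch.
#' @param base reference envelope semi-axes (cm) at `n_ref` berries.
#' @param n_ref berry count the reference envelope corresponds to.
#' @return Length-3 envelope semi-axes.
#' @export
scaled_envelope <- function(n_berries, base = c(5.5, 3.0, 2.4),
                            n_ref = 60) {
  base * max(1e-6, n_berries / n_ref)^(1 / 3)
}

#' @export
print.berry_cluster <- function(x, ...) {
  cat(sprintf("<berry_cluster: %d berries, radius %.2f cm>\n",
              x$n_berries, x$radius))
  invisible(x)
}

#' Union-of-spheres volume by slice-wise voxel counting
#'
#' Counts voxel centres on a regular grid that fall inside at least one
#' sphere, slice by slice along z to bound memory.
#'
#' @param centers n x 3 sphere centres (cm).
#' @param radius common sphere radius (cm).
#' @param resolution_cm voxel edge length.
#' @return Volume in cm^3 (0 for an empty cluster).
#' @export
union_of_spheres_volume <- function(centers, radius, resolution_cm = 0.01) {
  centers <- as.matrix(centers)
  if (nrow(centers) == 0) return(0)
  stop_if_not_positive(radius, "radius")
  stop_if_not_positive(resolution_cm, "resolution_cm")
  h <- resolution_cm
  lo <- apply(centers, 2, min) - radius - h
  hi <- apply(centers, 2, max) + radius + h
  xs <- seq(lo[1] + h / 2, hi[1], by = h)
  ys <- seq(lo[2] + h / 2, hi[2], by = h)
  zs <- seq(lo[3] + h / 2, hi[3], by = h)
  r2 <- radius^2
  count <- 0
  for (z in zs) {
    dz2 <- (z - centers[, 3])^2
    act <- which(dz2 < r2)
    if (length(act) == 0) next
    sl <- matrix(FALSE, length(xs), length(ys))
    for (i in act) {
      rd2 <- r2 - dz2[i]
      rd <- sqrt(rd2)
      ix <- which(xs >= centers[i, 1] - rd & xs <= centers[i, 1] + rd)
      iy <- which(ys >= centers[i, 2] - rd & ys <= centers[i, 2] + rd)
      if (length(ix) == 0 || length(iy) == 0) next
      dx2 <- (xs[ix] - centers[i, 1])^2
      dy2 <- (ys[iy] - centers[i, 2])^2
      sl[ix, iy] <- sl[ix, iy] | (outer(dx2, dy2, `+`) <= rd2)
    }
    count <- count + sum(sl)
  }
  count * h^3
}

#' True (union-of-spheres) volume of a berry cluster
#'
#' @param cluster a `berry_cluster`.
#' @param resolution_cm voxel edge length for the volume integration.
#' @return Volume in cm^3.
#' @export
cluster_volume <- function(cluster, resolution_cm = 0.01) {
  stopifnot(inherits(cluster, "berry_cluster"))
  if (cluster$n_berries == 0) return(0)
  if (cluster$n_berries == 1) return(4 / 3 * pi * cluster$radius^3)
  union_of_spheres_volume(cluster$centers, cluster$radius, resolution_cm)
}

# vectorized HSV -> RGB (hexcone model), all components on [0,1]
hsv_to_rgb_mat <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- g <- b <- numeric(length(h))
  m <- i %% 6
  sel <- m == 0; r[sel] <- v[sel]; g[sel] <- t[sel]; b[sel] <- p[sel]
  sel <- m == 1; r[sel] <- q[sel]; g[sel] <- v[sel]; b[sel] <- p[sel]
  sel <- m == 2; r[sel] <- p[sel]; g[sel] <- v[sel]; b[sel] <- t[sel]
  sel <- m == 3; r[sel] <- p[sel]; g[sel] <- q[sel]; b[sel] <- v[sel]
  sel <- m == 4; r[sel] <- t[sel]; g[sel] <- p[sel]; b[sel] <- v[sel]
  sel <- m == 5; r[sel] <- v[sel]; g[sel] <- p[sel]; b[sel] <- q[sel]
  cbind(r, g, b)
}

sample_band_rgb <- function(n, band) {
  h <- runif(n, band$h[1], band$h[2])
  s <- runif(n, band$s[1], band$s[2])
  v <- runif(n, band$v[1], band$v[2])
  hsv_to_rgb_mat(h, s, v)
}

#' Render a synthetic bunch image with ground truth
#'
#' Projects the cluster along z onto the image plane: berry pixels are
#' those inside any projected berry disk, drawn from the dark-purple HSV
#' band; the rest of the frame is canopy-green background. Under the FC
#' treatment, green elliptical leaf occluders are drawn over the bunch
#' one at a time until the realized cover fraction of bunch pixels is
#' hidden. A neutral reference bar of known physical length is rendered
#' along the bottom of the frame and its pixel length recorded in the
#' scene metadata (marker re-detection is out of scope).
#'
#' @param cluster a `berry_cluster`.
#' @param occlusion an [occlusion_config()].
#' @param pixels_per_cm image scale.
#' @param colour_model see [default_colour_model()].
#' @param seed integer seed.
#' @param ruler_cm physical length of the reference bar.
#' @param margin_cm clear margin around the bunch.
#' @param density_g_per_cm3 density used for the ground-truth mass.
#' @param mass_noise_cv coefficient of variation of the multiplicative
#'   mass noise (`mass = density * volume * (1 + noise)`).
#' @param truth_resolution_cm voxel resolution of the ground-truth
#'   union-of-spheres volume integration.
#' @return List with `scene` (class `rgb_scene`: `image` array in
#'   `[0,1]`, `pixels_per_cm`, `ruler_px`, `ruler_cm`) and `truth`
#'   (class `scene_ground_truth`: `true_mask`, `true_area_cm2`,
#'   `unoccluded_area_cm2`, `true_volume_cm3`, `true_mass_g`).
#' @export
render_bunch_image <- function(cluster, occlusion = occlusion_config("LR"),
                               pixels_per_cm = 10,
                               colour_model = default_colour_model(),
                               seed = 1L, ruler_cm = 10, margin_cm = 1,
                               density_g_per_cm3 = 1.0,
                               mass_noise_cv = 0,
                               truth_resolution_cm = 0.02) {
  stopifnot(inherits(cluster, "berry_cluster"),
            inherits(occlusion, "occlusion_config"))
  stop_if_not_positive(pixels_per_cm, "pixels_per_cm")
  r <- cluster$radius
  if (cluster$n_berries > 0) {
    cx <- range(cluster$centers[, 1])
    cy <- range(cluster$centers[, 2])
  } else {
    cx <- cy <- c(-1, 1)
  }
  x0 <- cx[1] - r - margin_cm
  x1 <- max(cx[2] + r + margin_cm, x0 + ruler_cm + 1)
  y0 <- cy[1] - r - margin_cm - 1.2  # room for the reference bar
  y1 <- cy[2] + r + margin_cm
  nc <- max(8L, ceiling((x1 - x0) * pixels_per_cm))
  nr <- max(8L, ceiling((y1 - y0) * pixels_per_cm))
  # pixel centre coordinates; row 1 = top of frame
  px <- x0 + (seq_len(nc) - 0.5) / pixels_per_cm
  py <- y1 - (seq_len(nr) - 0.5) / pixels_per_cm

  berry <- matrix(FALSE, nr, nc)
  if (cluster$n_berries > 0) {
    for (i in seq_len(cluster$n_berries)) {
      cxy <- cluster$centers[i, 1:2]
      ix <- which(abs(px - cxy[1]) <= r)
      iy <- which(abs(py - cxy[2]) <= r)
      if (length(ix) == 0 || length(iy) == 0) next
      d2 <- outer((py[iy] - cxy[2])^2, (px[ix] - cxy[1])^2, `+`)
      berry[iy, ix] <- berry[iy, ix] | (d2 <= r^2)
    }
  }

  out <- with_rng_seed(seed, {
    occluded <- matrix(FALSE, nr, nc)
    u_cover <- runif(1)
    target <- realized_cover(occlusion$leaf_cover_fraction, u_cover)
    n_berry_px <- sum(berry)
    if (target > 0 && n_berry_px > 0) {
      bidx <- which(berry)
      for (k in seq_len(400L)) {
        hidden <- sum(berry & occluded) / n_berry_px
        if (hidden >= target) break
        ctr <- bidx[sample.int(length(bidx), 1)]
        crow <- (ctr - 1) %% nr + 1
        ccol <- (ctr - 1) %/% nr + 1
        ax <- runif(1, 0.5, 1.6) * pixels_per_cm
        ay <- runif(1, 0.3, 1.0) * pixels_per_cm
        th <- runif(1, 0, pi)
        ix <- pmax(1, ceiling(ccol - ax - ay)):pmin(nc, floor(ccol + ax + ay))
        iy <- pmax(1, ceiling(crow - ax - ay)):pmin(nr, floor(crow + ax + ay))
        dx <- outer(rep(1, length(iy)), ix - ccol)
        dy <- outer(iy - crow, rep(1, length(ix)))
        xr <- dx * cos(th) + dy * sin(th)
        yr <- -dx * sin(th) + dy * cos(th)
        occluded[iy, ix] <- occluded[iy, ix] |
          ((xr / ax)^2 + (yr / ay)^2 <= 1)
      }
    }
    visible <- berry & !occluded

    img <- array(0, dim = c(nr, nc, 3))
    n_px <- nr * nc
    bg <- sample_band_rgb(n_px, colour_model$background)
    img[, , 1] <- bg[, 1]; img[, , 2] <- bg[, 2]; img[, , 3] <- bg[, 3]
    paint <- function(img, mask, band) {
      idx <- which(mask)
      if (length(idx) == 0) return(img)
      cols <- sample_band_rgb(length(idx), band)
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[idx] <- cols[, ch]
        img[, , ch] <- pl
      }
      img
    }
    img <- paint(img, visible, colour_model$berry)
    img <- paint(img, occluded, colour_model$leaf)
    # reference bar: ruler_cm long, 0.4 cm tall, bottom-left corner
    bar_cols <- which(px >= x0 + 0.5 & px <= x0 + 0.5 + ruler_cm)
    bar_rows <- which(py <= y0 + 0.9 & py >= y0 + 0.5)
    bar <- matrix(FALSE, nr, nc)
    bar[bar_rows, bar_cols] <- TRUE
    bar <- bar & !visible
    img <- paint(img, bar, colour_model$ruler)

    vol <- cluster_volume(cluster, truth_resolution_cm)
    mass <- density_g_per_cm3 * vol *
      (1 + if (mass_noise_cv > 0) rnorm(1, 0, mass_noise_cv) else 0)
    list(
      scene = structure(list(
        image = img, pixels_per_cm = pixels_per_cm,
        ruler_px = ruler_cm * pixels_per_cm, ruler_cm = ruler_cm,
        seed = as.integer(seed)), class = "rgb_scene"),
      truth = structure(list(
        true_mask = visible,
        true_area_cm2 = sum(visible) / pixels_per_cm^2,
        unoccluded_area_cm2 = sum(berry) / pixels_per_cm^2,
        true_volume_cm3 = vol,
        true_mass_g = max(0, mass),
        realized_cover = if (n_berry_px > 0)
          sum(berry & occluded) / n_berry_px else 0),
        class = "scene_ground_truth"))
  })
  out
}

#' @export
print.rgb_scene <- function(x, ...) {
  cat(sprintf("<rgb_scene: %d x %d px, %.1f px/cm>\n",
              nrow(x$image), ncol(x$image), x$pixels_per_cm))
  invisible(x)
}

#' Sample a synthetic bunch point cloud with ground truth
#'
#' Points are sampled uniformly on each berry's sphere surface, displaced
#' by isotropic Gaussian sensor noise, and coloured from the berry HSV
#' band (RGB 0..255). Optional canopy points are scattered in a slab
#' behind the bunch with green-band colours. Under the FC treatment,
#' spherical leaf occluders remove berry points until the realized cover
#' fraction is hidden.
#'
#' @param cluster a `berry_cluster`.
#' @param points_per_berry number of surface samples per berry (>= 4).
#' @param colour_model see [default_colour_model()].
#' @param sensor_noise_sd_cm isotropic noise standard deviation.
#' @param occlusion an [occlusion_config()].
#' @param n_canopy_points background canopy points to add.
#' @param interior_points_per_berry uniform samples inside each berry
#'   ball (default 0: sensor-like surface-only cloud). Surface plus
#'   interior sampling is the dense volumetric mode used to validate
#'   volume recovery; a small alpha (about 0.3 times the berry radius)
#'   then recovers the union-of-spheres volume closely.
#' @param seed integer seed.
#' @param density_g_per_cm3,mass_noise_cv ground-truth mass model.
#' @param truth_resolution_cm voxel resolution of the ground-truth volume.
#' @return List with `cloud` (a labelled `bunch_point_cloud`) and `truth`
#'   (`scene_ground_truth` without an image mask).
#' @export
sample_bunch_point_cloud <- function(cluster, points_per_berry = 300L,
                                     colour_model = default_colour_model(),
                                     sensor_noise_sd_cm = 0.02,
                                     occlusion = occlusion_config("LR"),
                                     n_canopy_points = 0L,
                                     interior_points_per_berry = 0L,
                                     seed = 1L,
                                     density_g_per_cm3 = 1.0,
                                     mass_noise_cv = 0,
                                     truth_resolution_cm = 0.02) {
  stopifnot(inherits(cluster, "berry_cluster"))
  if (points_per_berry < 4) stop("points_per_berry must be >= 4")
  if (sensor_noise_sd_cm < 0) stop("sensor_noise_sd_cm must be >= 0")
  with_rng_seed(seed, {
    n <- cluster$n_berries * points_per_berry
    if (cluster$n_berries > 0) {
      dirs <- matrix(rnorm(3 * n), n, 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      ctr <- cluster$centers[rep(seq_len(cluster$n_berries),
                                 each = points_per_berry), , drop = FALSE]
      pts <- ctr + cluster$radius * dirs
      if (interior_points_per_berry > 0) {
        ni <- cluster$n_berries * interior_points_per_berry
        di <- matrix(rnorm(3 * ni), ni, 3)
        di <- di / sqrt(rowSums(di^2))
        ctri <- cluster$centers[rep(seq_len(cluster$n_berries),
                                    each = interior_points_per_berry), ,
                                drop = FALSE]
        pts <- rbind(pts, ctri + cluster$radius * runif(ni)^(1 / 3) * di)
        n <- n + ni
      }
      if (sensor_noise_sd_cm > 0)
        pts <- pts + matrix(rnorm(3 * n, 0, sensor_noise_sd_cm), n, 3)
      cols <- round(sample_band_rgb(n, colour_model$berry) * 255)
      lab <- rep("berry", n)
    } else {
      pts <- matrix(numeric(0), 0, 3)
      cols <- matrix(numeric(0), 0, 3)
      lab <- character(0)
    }
    # FC: remove berry points hidden behind spherical leaf occluders
    u_cover <- runif(1)
    target <- realized_cover(occlusion$leaf_cover_fraction, u_cover)
    if (target > 0 && nrow(pts) > 0) {
      keep <- rep(TRUE, nrow(pts))
      n0 <- nrow(pts)
      for (k in seq_len(200L)) {
        if (1 - sum(keep) / n0 >= target) break
        anchor <- pts[sample.int(n0, 1), ]
        rad <- runif(1, 0.6, 1.4)
        d2 <- (pts[, 1] - anchor[1])^2 + (pts[, 2] - anchor[2])^2 +
              (pts[, 3] - anchor[3])^2
        keep <- keep & d2 > rad^2
      }
      pts <- pts[keep, , drop = FALSE]
      cols <- cols[keep, , drop = FALSE]
      lab <- lab[keep]
    }
    if (n_canopy_points > 0) {
      env <- cluster$envelope
      cp <- cbind(runif(n_canopy_points, -2 * env[1], 2 * env[1]),
                  runif(n_canopy_points, -2 * env[2], 2 * env[2]),
                  runif(n_canopy_points, -env[3] - 3, -env[3] - 0.5))
      cc <- round(sample_band_rgb(n_canopy_points, colour_model$leaf) * 255)
      pts <- rbind(pts, cp)
      cols <- rbind(cols, cc)
      lab <- c(lab, rep("canopy", n_canopy_points))
    }
    vol <- cluster_volume(cluster, truth_resolution_cm)
    mass <- density_g_per_cm3 * vol *
      (1 + if (mass_noise_cv > 0) rnorm(1, 0, mass_noise_cv) else 0)
    list(cloud = bunch_point_cloud(pts, cols, lab),
         truth = structure(list(
           true_mask = NULL,
           true_area_cm2 = NA_real_,
           true_volume_cm3 = vol,
           true_mass_g = max(0, mass)), class = "scene_ground_truth"))
  })
}

#' Reference table of bunch mass and displacement volume
#'
#' `mass_i = density * volume_i + eps_i` with Gaussian noise, emulating
#' laboratory mass/water-displacement reference measurements (1 mL is
#' taken as 1 cm^3 throughout).
#'
#' @param volumes_cm3 per-sample volumes.
#' @param density_g_per_cm3 fruit density.
#' @param noise_sd_g standard deviation of the mass noise in grams.
#' @param seed integer seed.
#' @return Data frame (`sample_id`, `volume_ml`, `mass_g`) of class
#'   `reference_table`.
#' @export
generate_reference_table <- function(volumes_cm3, density_g_per_cm3 = 1.0,
                                     noise_sd_g = 0, seed = 1L) {
  stop_if_not_positive(density_g_per_cm3, "density_g_per_cm3")
  if (noise_sd_g < 0) stop("noise_sd_g must be >= 0")
  n <- length(volumes_cm3)
  mass <- with_rng_seed(seed,
    density_g_per_cm3 * volumes_cm3 +
      if (noise_sd_g > 0) rnorm(n, 0, noise_sd_g) else 0)
  out <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                    volume_ml = as.numeric(volumes_cm3),
                    mass_g = as.numeric(mass))
  class(out) <- c("reference_table", "data.frame")
  out
}

#' Mass-noise level for a target mass-volume r-squared
#'
#' Uses the signal-to-total variance identity
#' `r2 ~ var(signal) / (var(signal) + sd^2)`, so
#' `sd = sd(density * volume) * sqrt((1 - r2) / r2)`.
#'
#' @param volumes_cm3 per-sample volumes.
#' @param density_g_per_cm3 fruit density.
#' @param target_r2 desired coefficient of determination in (0, 1].
#' @return Noise standard deviation in grams.
#' @export
noise_sd_for_target_r2 <- function(volumes_cm3, density_g_per_cm3 = 1.0,
                                   target_r2 = 0.971) {
  if (target_r2 <= 0 || target_r2 > 1) stop("target_r2 must be in (0, 1]")
  sd(density_g_per_cm3 * volumes_cm3) * sqrt((1 - target_r2) / target_r2)
}

#' Apply a multiplicative sensor volume bias
#'
#' Emulates the systematic volume overestimation of a consumer
#' structured-light depth sensor: `bias_factor * volume + noise`. The
#' default factor 1.212 is the overestimation ratio observed between
#' depth-sensor and displacement volume means at bunch level.
#'
#' @param volume_cm3 true volume(s), >= 0.
#' @param bias_factor multiplicative bias (> 0).
#' @param noise_sd_cm3 additive Gaussian noise SD.
#' @param seed integer seed.
#' @return Biased volume(s); negatives are clamped to 0 with a warning.
#' @export
apply_sensor_bias <- function(volume_cm3, bias_factor = 1.212,
                              noise_sd_cm3 = 0, seed = 1L) {
  if (any(volume_cm3 < 0)) stop("volume must be >= 0")
  stop_if_not_positive(bias_factor, "bias_factor")
  if (noise_sd_cm3 < 0) stop("noise_sd_cm3 must be >= 0")
  out <- with_rng_seed(seed,
    bias_factor * volume_cm3 +
      if (noise_sd_cm3 > 0) rnorm(length(volume_cm3), 0, noise_sd_cm3) else 0)
  if (any(out < 0)) {
    warning("negative biased volume clamped to 0")
    out[out < 0] <- 0
  }
  out
}
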