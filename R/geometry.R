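#' Triangle mesh constructor
#'
#' A minimal triangle-mesh container: vertex coordinates in centimetres
#' and faces as triples of vertex indices. Winding is taken as given;
#' [mesh_volume()] uses the absolute signed volume so either consistent
#' orientation works.
#'
#' @param vertices numeric matrix, n x 3 (cm).
#' @param faces integer matrix, m x 3 of 1-based vertex indices.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3) stop("vertices must be an n x 3 matrix")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0) {
    if (ncol(faces) != 3) stop("faces must be an m x 3 matrix")
    if (any(faces < 1L) || any(faces > nrow(vertices)))
      stop("face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh: %d vertices, %d faces, %s>\n",
              nrow(x$vertices), nrow(x$faces),
              if (is_watertight(x)) "watertight" else "open"))
  invisible(x)
}

#' Point cloud with per-point RGB colour
#'
#' @param points numeric matrix, n x 3 (cm).
#' @param colours numeric matrix, n x 3, RGB in 0..255. Defaults to grey.
#' @param label optional character vector of per-point labels (e.g. the
#'   generating class of a synthetic point).
#' @return An object of class `bunch_point_cloud`.
#' @export
bunch_point_cloud <- function(points, colours = NULL, label = NULL) {
  points <- as.matrix(points)
  if (length(points) == 0) points <- matrix(numeric(0), 0, 3)
  storage.mode(points) <- "double"
  if (ncol(points) != 3) stop("points must be an n x 3 matrix")
  dimnames(points) <- NULL
  n <- nrow(points)
  if (is.null(colours)) colours <- matrix(128, n, 3)
  colours <- as.matrix(colours)
  if (length(colours) == 0) colours <- matrix(numeric(0), 0, 3)
  dimnames(colours) <- NULL
  if (nrow(colours) != n || ncol(colours) != 3)
    stop("colours must be congruent with points (n x 3)")
  if (n > 0 && (min(colours) < 0 || max(colours) > 255))
    stop("colours must lie in [0, 255]")
  if (!is.null(label) && length(label) != n)
    stop("label must have one entry per point")
  structure(list(points = points, colours = colours, label = label),
            class = "bunch_point_cloud")
}

#' @export
print.bunch_point_cloud <- function(x, ...) {
  cat(sprintf("<bunch_point_cloud: %d points>\n", nrow(x$points)))
  invisible(x)
}

as_point_matrix <- function(x) {
  if (inherits(x, "bunch_point_cloud")) return(x$points)
  if (inherits(x, "tri_mesh")) return(x$vertices)
  m <- as.matrix(x)
  if (ncol(m) != 3) stop("expected an n x 3 coordinate matrix")
  storage.mode(m) <- "double"
  m
}

#' Delaunay tetrahedralization of a 3-D point set
#'
#' Computes the full Delaunay tetrahedralization together with each
#' tetrahedron's circumradius and volume; [alpha_complex_volume()] and
#' [tune_alpha()] filter this structure at one or many alpha values
#' without recomputing it. Near-degenerate inputs (for example exactly
#' cospherical samples) are retried with a deterministic jitter of
#' 1e-9 times the bounding-box diagonal.
#'
#' @param points n x 3 numeric matrix, a `bunch_point_cloud`, or a
#'   `tri_mesh` (its vertices are used).
#' @param jitter_seed integer seed for the deterministic fallback jitter.
#' @return List with `tets` (t x 4 vertex indices), `circumradius` and
#'   `volume` (length t), of class `delaunay_tets`.
#' @export
delaunay_tets <- function(points, jitter_seed = 1L) {
  pts <- as_point_matrix(points)
  pts <- pts[!duplicated(pts), , drop = FALSE]
  if (nrow(pts) < 4) stop("need at least 4 distinct points")
  diag <- sqrt(sum((apply(pts, 2, max) - apply(pts, 2, min))^2))
  # a valid tetrahedralization partitions the hull: check the total
  # volume against an independent quickhull computation
  consistent <- function(res, p) {
    hull <- .convex_hull_volume_cpp(p)
    is.finite(hull) && hull > 0 &&
      abs(sum(res$volume) - hull) <= 1e-9 * hull
  }
  res <- tryCatch(.delaunay_tets_cpp(pts), error = function(e) e)
  if (!inherits(res, "error") && !consistent(res, pts))
    res <- simpleError("inconsistent tetrahedralization (degenerate ties)")
  if (inherits(res, "error")) {
    msg <- conditionMessage(res)
    if (grepl("degenerate input", msg)) stop(res)
    # numerical degeneracy: deterministic jitter then retry
    for (amp in c(1e-6, 1e-4, 1e-3) * diag) {
      jpts <- with_rng_seed(jitter_seed,
        pts + matrix(runif(length(pts), -amp, amp), nrow(pts), 3))
      res <- tryCatch(.delaunay_tets_cpp(jpts), error = function(e) e)
      if (!inherits(res, "error") && consistent(res, jpts)) break
      if (!inherits(res, "error"))
        res <- simpleError("inconsistent tetrahedralization after jitter")
    }
    if (inherits(res, "error")) stop(res)
  }
  structure(res, class = "delaunay_tets", n_points = nrow(pts))
}

#' Alpha-complex volume of a point cloud
#'
#' Retains the Delaunay tetrahedra whose circumradius is at most `alpha`
#' and sums their volumes. As `alpha` grows the kept complex grows
#' monotonically towards the full Delaunay tetrahedralization, whose
#' total volume is the convex-hull volume; small alpha carves out the
#' concave structure of the cloud. `alpha` is in the units of the point
#' coordinates (cm throughout this package).
#'
#' @param points n x 3 matrix or `bunch_point_cloud`; ignored when `tets`
#'   is supplied.
#' @param alpha positive circumradius threshold (cm).
#' @param tets optional precomputed [delaunay_tets()] result.
#' @return Object of class `alpha_complex_result` with fields `alpha`,
#'   `kept_tetrahedra` (row indices into the tetrahedralization) and
#'   `volume_cm3`.
#' @export
alpha_complex_volume <- function(points, alpha, tets = NULL) {
  stop_if_not_positive(alpha, "alpha")
  if (is.null(tets)) {
    pts <- as_point_matrix(points)
    pts <- pts[!duplicated(pts), , drop = FALSE]
    if (nrow(pts) < 4) {
      warning("fewer than 4 distinct points; alpha-complex volume is 0")
      return(structure(list(alpha = alpha, kept_tetrahedra = integer(0),
                            volume_cm3 = 0), class = "alpha_complex_result"))
    }
    tets <- tryCatch(delaunay_tets(pts), error = function(e) e)
    if (inherits(tets, "error")) {
      if (grepl("degenerate input", conditionMessage(tets))) {
        warning("degenerate (coplanar) input; alpha-complex volume is 0")
        return(structure(list(alpha = alpha, kept_tetrahedra = integer(0),
                              volume_cm3 = 0),
                         class = "alpha_complex_result"))
      }
      stop(tets)
    }
  }
  keep <- which(tets$circumradius <= alpha)
  structure(list(alpha = alpha, kept_tetrahedra = keep,
                 volume_cm3 = sum(tets$volume[keep])),
            class = "alpha_complex_result")
}

#' @export
print.alpha_complex_result <- function(x, ...) {
  cat(sprintf("<alpha complex: alpha = %g cm, %d tetrahedra, %.4f cm^3>\n",
              x$alpha, length(x$kept_tetrahedra), x$volume_cm3))
  invisible(x)
}

#' Convex-hull volume (independent quickhull implementation)
#'
#' @param points n x 3 matrix or `bunch_point_cloud`.
#' @return Hull volume (0 for degenerate input).
#' @export
convex_hull_volume <- function(points) {
  pts <- as_point_matrix(points)
  if (nrow(pts) < 4) return(0)
  .convex_hull_volume_cpp(pts)
}

mesh_edge_table <- function(faces) {
  if (nrow(faces) == 0)
    return(data.frame(a = integer(0), b = integer(0), count = integer(0)))
  e <- rbind(faces[, c(1, 2), drop = FALSE],
             faces[, c(2, 3), drop = FALSE],
             faces[, c(3, 1), drop = FALSE])
  a <- pmin(e[, 1], e[, 2])
  b <- pmax(e[, 1], e[, 2])
  key <- paste(a, b)
  tab <- table(key)
  parts <- strsplit(names(tab), " ", fixed = TRUE)
  data.frame(a = as.integer(vapply(parts, `[`, "", 1)),
             b = as.integer(vapply(parts, `[`, "", 2)),
             count = as.integer(tab))
}

#' Test whether a mesh is watertight
#'
#' A mesh is watertight (a closed surface) when every edge is shared by
#' exactly two faces.
#'
#' @param mesh a `tri_mesh`.
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (nrow(mesh$faces) == 0) return(FALSE)
  all(mesh_edge_table(mesh$faces)$count == 2L)
}

#' Enclosed volume of a watertight mesh
#'
#' Divergence-theorem (signed tetrahedron) volume: the absolute value of
#' the sum of signed tetrahedra spanned by each face and the origin,
#' `|sum det(v0, v1, v2)| / 6`. Invariant to rigid motions.
#'
#' @param mesh a watertight `tri_mesh`.
#' @return Volume in cm^3.
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  et <- mesh_edge_table(mesh$faces)
  open_edges <- et[et$count != 2L, , drop = FALSE]
  if (nrow(mesh$faces) == 0 || nrow(open_edges) > 0) {
    shown <- head(open_edges, 5)
    stop(sprintf(
      "mesh is not watertight: %d offending edge(s), e.g. %s",
      max(1L, nrow(open_edges)),
      paste(sprintf("(%d,%d)", shown$a, shown$b), collapse = " ")))
  }
  v <- mesh$vertices
  f <- mesh$faces
  p0 <- v[f[, 1], , drop = FALSE]
  p1 <- v[f[, 2], , drop = FALSE]
  p2 <- v[f[, 3], , drop = FALSE]
  s <- p0[, 1] * (p1[, 2] * p2[, 3] - p1[, 3] * p2[, 2]) -
       p0[, 2] * (p1[, 1] * p2[, 3] - p1[, 3] * p2[, 1]) +
       p0[, 3] * (p1[, 1] * p2[, 2] - p1[, 2] * p2[, 1])
  abs(sum(s)) / 6
}

#' Crop a mesh or point cloud to an axis-aligned box
#'
#' Retains exactly the vertices/points inside the box; mesh faces that
#' reference a removed vertex are dropped.
#'
#' @param geometry a `tri_mesh` or `bunch_point_cloud`.
#' @param lo,hi numeric length-3 lower/upper box corners (cm).
#' @return Cropped object of the same class.
#' @export
crop_box <- function(geometry, lo, hi) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (length(lo) != 3 || length(hi) != 3 || any(!is.finite(c(lo, hi))))
    stop("lo and hi must be finite length-3 vectors")
  if (any(lo > hi)) stop("invalid box: lo > hi")
  if (inherits(geometry, "bunch_point_cloud")) {
    p <- geometry$points
    keep <- p[, 1] >= lo[1] & p[, 1] <= hi[1] &
            p[, 2] >= lo[2] & p[, 2] <= hi[2] &
            p[, 3] >= lo[3] & p[, 3] <= hi[3]
    if (!any(keep)) warning("crop_box: no points inside the box")
    return(bunch_point_cloud(p[keep, , drop = FALSE],
                             geometry$colours[keep, , drop = FALSE],
                             if (is.null(geometry$label)) NULL
                             else geometry$label[keep]))
  }
  if (inherits(geometry, "tri_mesh")) {
    p <- geometry$vertices
    keep <- p[, 1] >= lo[1] & p[, 1] <= hi[1] &
            p[, 2] >= lo[2] & p[, 2] <= hi[2] &
            p[, 3] >= lo[3] & p[, 3] <= hi[3]
    if (!any(keep)) {
      warning("crop_box: no vertices inside the box")
      return(tri_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3)))
    }
    newidx <- cumsum(keep)
    fkeep <- keep[geometry$faces[, 1]] & keep[geometry$faces[, 2]] &
             keep[geometry$faces[, 3]]
    faces <- geometry$faces[fkeep, , drop = FALSE]
    faces[] <- newidx[faces]
    return(tri_mesh(p[keep, , drop = FALSE], faces))
  }
  stop("geometry must be a tri_mesh or bunch_point_cloud")
}

# boundary faces (outward-oriented) of a set of Delaunay tetrahedra
alpha_boundary_mesh <- function(pts, tetmat) {
  f <- rbind(tetmat[, c(2, 3, 4), drop = FALSE],
             tetmat[, c(1, 3, 4), drop = FALSE],
             tetmat[, c(1, 2, 4), drop = FALSE],
             tetmat[, c(1, 2, 3), drop = FALSE])
  opp <- c(tetmat[, 1], tetmat[, 2], tetmat[, 3], tetmat[, 4])
  s1 <- pmin(f[, 1], f[, 2], f[, 3])
  s3 <- pmax(f[, 1], f[, 2], f[, 3])
  s2 <- f[, 1] + f[, 2] + f[, 3] - s1 - s3
  key <- paste(s1, s2, s3)
  cnt <- table(key)
  bnd <- which(key %in% names(cnt)[cnt == 1L])
  faces <- f[bnd, , drop = FALSE]
  oppv <- opp[bnd]
  # orient each face so its normal points away from the owning tetrahedron
  a <- pts[faces[, 1], , drop = FALSE]
  b <- pts[faces[, 2], , drop = FALSE]
  c3 <- pts[faces[, 3], , drop = FALSE]
  d <- pts[oppv, , drop = FALSE]
  u <- b - a; w <- c3 - a; q <- d - a
  det <- u[, 1] * (w[, 2] * q[, 3] - w[, 3] * q[, 2]) -
         u[, 2] * (w[, 1] * q[, 3] - w[, 3] * q[, 1]) +
         u[, 3] * (w[, 1] * q[, 2] - w[, 2] * q[, 1])
  flip <- det > 0
  tmp <- faces[flip, 2]
  faces[flip, 2] <- faces[flip, 3]
  faces[flip, 3] <- tmp
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(pts))
  remap[used] <- seq_along(used)
  faces[] <- remap[faces]
  tri_mesh(pts[used, , drop = FALSE], faces)
}

# number of connected components of a face set, connectivity via shared
# undirected edges (union-find)
face_components <- function(faces) {
  nf <- nrow(faces)
  if (nf == 0) return(0L)
  parent <- seq_len(nf)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  fid <- rep(seq_len(nf), 3)
  groups <- split(fid, key)
  for (g in groups) {
    if (length(g) > 1) {
      r <- find(g[1])
      for (x in g[-1]) {
        rx <- find(x)
        if (rx != r) parent[rx] <- r
      }
    }
  }
  length(unique(vapply(seq_len(nf), find, 1L)))
}

# single evaluation of the auto-alpha acceptance rule
.reconstruction_at_alpha <- function(pts, tets, alpha) {
  keep <- tets$circumradius <= alpha
  if (!any(keep)) return(NULL)
  mesh <- alpha_boundary_mesh(pts, tets$tets[keep, , drop = FALSE])
  et <- mesh_edge_table(mesh$faces)
  if (any(et$count != 2L)) return(NULL)          # non-manifold boundary
  if (face_components(mesh$faces) != 1L) return(NULL)  # internal voids
  # the complex itself must also be one component: a single closed outer
  # boundary plus one component is implied by the two checks above for
  # solid complexes, but guard against disjoint blobs sharing no surface
  mesh
}

#' Reconstruct a watertight surface from points or an open mesh
#'
#' Contract: the output passes [is_watertight()] with consistent outward
#' orientation, or an explicit error is raised. The default backend
#' extracts the boundary of the alpha complex of the input points. When
#' `alpha` is `NULL` the smallest alpha is chosen (by scanning quantiles
#' of the Delaunay circumradius distribution) for which the boundary is a
#' single closed manifold surface, i.e. the smallest alpha producing one
#' solid component without internal voids; if no finite alpha passes, the
#' convex hull (alpha of infinity) is used.
#'
#' @param x point matrix, `bunch_point_cloud`, or (open) `tri_mesh`.
#' @param alpha circumradius threshold in cm, or `NULL` for automatic
#'   selection.
#' @return A watertight `tri_mesh`.
#' @export
reconstruct_watertight <- function(x, alpha = NULL) {
  pts <- as_point_matrix(x)
  pts <- pts[!duplicated(pts), , drop = FALSE]
  if (nrow(pts) < 4)
    stop("reconstruction failed: need at least 4 distinct points")
  tets <- tryCatch(delaunay_tets(pts), error = function(e)
    stop("reconstruction failed: degenerate input (", conditionMessage(e),
         ")", call. = FALSE))
  if (!is.null(alpha)) {
    stop_if_not_positive(alpha, "alpha")
    mesh <- .reconstruction_at_alpha(pts, tets, alpha)
    if (is.null(mesh))
      stop("reconstruction failed: boundary at alpha = ", alpha,
           " is not a single closed surface; increase alpha")
    return(mesh)
  }
  cand <- sort(unique(c(
    quantile(tets$circumradius, probs = seq(0.5, 1, by = 0.02), names = FALSE),
    max(tets$circumradius))))
  for (a in cand) {
    mesh <- .reconstruction_at_alpha(pts, tets, a)
    if (!is.null(mesh)) return(mesh)
  }
  stop("reconstruction failed: no alpha yields a closed manifold surface")
}

#' Filter a point cloud by an RGB colour box
#'
#' Retains points whose colour lies inside the axis-aligned RGB box
#' `[lo, hi]` (componentwise, inclusive).
#'
#' @param cloud a `bunch_point_cloud`.
#' @param rgb_lo,rgb_hi numeric length-3, 0..255, `lo <= hi` componentwise.
#' @return Filtered `bunch_point_cloud`.
#' @export
filter_points_by_colour <- function(cloud, rgb_lo, rgb_hi) {
  stopifnot(inherits(cloud, "bunch_point_cloud"))
  rgb_lo <- as.numeric(rgb_lo); rgb_hi <- as.numeric(rgb_hi)
  if (length(rgb_lo) != 3 || length(rgb_hi) != 3 || any(rgb_lo > rgb_hi))
    stop("need length-3 bounds with lo <= hi componentwise")
  cl <- cloud$colours
  keep <- cl[, 1] >= rgb_lo[1] & cl[, 1] <= rgb_hi[1] &
          cl[, 2] >= rgb_lo[2] & cl[, 2] <= rgb_hi[2] &
          cl[, 3] >= rgb_lo[3] & cl[, 3] <= rgb_hi[3]
  if (!any(keep)) message("filter_points_by_colour: no points retained")
  bunch_point_cloud(cloud$points[keep, , drop = FALSE],
                    cl[keep, , drop = FALSE],
                    if (is.null(cloud$label)) NULL else cloud$label[keep])
}

#' Fit an RGB colour box from example colours
#'
#' Per-channel quantile envelope `[q, 1 - q]` of the supplied colours,
#' the automatic analogue of choosing point-cloud colour thresholds by
#' hand on a training sample.
#'
#' @param colours n x 3 RGB matrix (0..255) of target-class points.
#' @param quantile tail fraction clipped per channel, in `[0, 0.5)`.
#' @return List with `rgb_lo` and `rgb_hi`.
#' @export
fit_colour_box <- function(colours, quantile = 0.01) {
  colours <- as.matrix(colours)
  if (nrow(colours) == 0) stop("no colours supplied")
  if (quantile < 0 || quantile >= 0.5) stop("quantile must be in [0, 0.5)")
  lo <- apply(colours, 2, stats::quantile, probs = quantile, names = FALSE)
  hi <- apply(colours, 2, stats::quantile, probs = 1 - quantile, names = FALSE)
  list(rgb_lo = lo, rgb_hi = hi)
}

#' Uniform point-cloud decimation
#'
#' Keeps every `factor`-th point, emulating the integer "cloud
#' decimation" thinning applied by RGB-D export tools.
#'
#' @param cloud a `bunch_point_cloud`.
#' @param factor integer >= 1.
#' @return Decimated `bunch_point_cloud`.
#' @export
decimate_cloud <- function(cloud, factor = 2L) {
  stopifnot(inherits(cloud, "bunch_point_cloud"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  idx <- seq(1L, nrow(cloud$points), by = factor)
  bunch_point_cloud(cloud$points[idx, , drop = FALSE],
                    cloud$colours[idx, , drop = FALSE],
                    if (is.null(cloud$label)) NULL else cloud$label[idx])
}

#' Tune alpha against reference volumes
#'
#' For each alpha on the grid, computes the alpha-complex volume of every
#' sample, regresses the reference volumes on the estimates by ordinary
#' least squares, and records the r-squared and the residual RMSE of that
#' regression. The selected alpha minimizes RMSE, with ties broken toward
#' higher r-squared and then toward smaller alpha. Grid points where the
#' estimated volumes are constant across samples leave r-squared
#' undefined and are excluded from selection.
#'
#' @param samples list of point matrices or `bunch_point_cloud`s.
#' @param reference_volumes_cm3 numeric vector of reference volumes, one
#'   per sample.
#' @param alpha_grid numeric vector of candidate alphas (cm).
#' @return Object of class `alpha_tuning_curve` with a `curve` data frame
#'   (`alpha`, `r2`, `rmse`) and `selected_alpha`.
#' @export
tune_alpha <- function(samples, reference_volumes_cm3, alpha_grid) {
  if (length(samples) < 3) stop("need at least 3 samples")
  if (length(reference_volumes_cm3) != length(samples))
    stop("one reference volume per sample required")
  if (length(alpha_grid) == 0) stop("alpha grid is empty")
  alpha_grid <- sort(unique(as.numeric(alpha_grid)))
  if (any(alpha_grid <= 0)) stop("alpha values must be positive")
  tets <- lapply(samples, delaunay_tets)
  vols <- vapply(tets, function(tt) {
    vapply(alpha_grid, function(a) sum(tt$volume[tt$circumradius <= a]),
           0)
  }, numeric(length(alpha_grid)))
  if (length(alpha_grid) == 1) vols <- matrix(vols, nrow = 1)
  r2 <- rmse <- rep(NA_real_, length(alpha_grid))
  for (i in seq_along(alpha_grid)) {
    est <- vols[i, ]
    if (stats::var(est) <= 0) next
    fit <- lm(reference_volumes_cm3 ~ est)
    rss <- sum(residuals(fit)^2)
    tss <- sum((reference_volumes_cm3 - mean(reference_volumes_cm3))^2)
    r2[i] <- if (tss > 0) 1 - rss / tss else NA_real_
    rmse[i] <- sqrt(mean(residuals(fit)^2))
  }
  ok <- which(!is.na(rmse))
  if (length(ok) == 0) stop("no alpha on the grid gave variable volumes")
  best <- ok[order(rmse[ok], -r2[ok], alpha_grid[ok])][1]
  structure(list(
    curve = data.frame(alpha = alpha_grid, r2 = r2, rmse = rmse),
    selected_alpha = alpha_grid[best],
    volumes = t(vols)), class = "alpha_tuning_curve")
}

#' @export
print.alpha_tuning_curve <- function(x, ...) {
  cat(sprintf("<alpha tuning: %d alphas, selected alpha = %g cm>\n",
              nrow(x$curve), x$selected_alpha))
  invisible(x)
}

#' Plot an alpha tuning curve (RMSE and r-squared vs alpha)
#'
#' @param x an `alpha_tuning_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.alpha_tuning_curve <- function(x, ...) {
  cur <- x$curve
  op <- par(mar = c(4, 4, 2, 4))
  on.exit(par(op))
  plot(cur$alpha, cur$rmse, type = "b", pch = 16, xlab = "alpha (cm)",
       ylab = "regression RMSE (cm^3)", ...)
  abline_v <- x$selected_alpha
  graphics::abline(v = abline_v, lty = 2, col = "grey40")
  par(new = TRUE)
  plot(cur$alpha, cur$r2, type = "b", pch = 1, col = "firebrick",
       axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
  axis(4, col.axis = "firebrick")
  graphics::mtext("r-squared", side = 4, line = 2.5, col = "firebrick")
  invisible(x)
}

#' Total bunch volume per vine
#'
#' Mean of the east- and west-facing side volumes, in cm^3.
#'
#' @param volume_east_cm3,volume_west_cm3 non-negative side volumes.
#' @return `(Ve + Vw) / 2`.
#' @export
tbvv <- function(volume_east_cm3, volume_west_cm3) {
  if (any(volume_east_cm3 < 0) || any(volume_west_cm3 < 0))
    stop("volumes must be non-negative")
  (volume_east_cm3 + volume_west_cm3) / 2
}
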