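# Independent brute-force oracles, written against the definitions rather
# than the package implementation.

# union-of-spheres volume: mark voxel centres of a full 3-D grid that lie
# inside any sphere (per-sphere window marking into one logical array)
voxel_union_oracle <- function(centers, radius, res = 0.02) {
  centers <- as.matrix(centers)
  if (nrow(centers) == 0) return(0)
  lo <- apply(centers, 2, min) - radius - res
  hi <- apply(centers, 2, max) + radius + res
  gx <- seq(lo[1] + res / 2, hi[1], by = res)
  gy <- seq(lo[2] + res / 2, hi[2], by = res)
  gz <- seq(lo[3] + res / 2, hi[3], by = res)
  occ <- array(FALSE, dim = c(length(gx), length(gy), length(gz)))
  r2 <- radius^2
  for (i in seq_len(nrow(centers))) {
    ix <- which(abs(gx - centers[i, 1]) <= radius)
    iy <- which(abs(gy - centers[i, 2]) <= radius)
    iz <- which(abs(gz - centers[i, 3]) <= radius)
    dx2 <- (gx[ix] - centers[i, 1])^2
    dy2 <- (gy[iy] - centers[i, 2])^2
    dz2 <- (gz[iz] - centers[i, 3])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    occ[ix, iy, iz] <- occ[ix, iy, iz] | (d2 <= r2)
  }
  sum(occ) * res^3
}

# Monte-Carlo enclosed volume of a CONVEX outward-oriented mesh: a point is
# inside iff it is on the inner side of every face plane
mc_convex_mesh_volume <- function(mesh, n = 1e6, seed = 1) {
  v <- mesh$vertices
  f <- mesh$faces
  lo <- apply(v, 2, min); hi <- apply(v, 2, max)
  set.seed(seed)
  p <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
             runif(n, lo[3], hi[3]))
  inside <- rep(TRUE, n)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c3 <- v[f[i, 3], ]
    nrm <- c((b[2] - a[2]) * (c3[3] - a[3]) - (b[3] - a[3]) * (c3[2] - a[2]),
             (b[3] - a[3]) * (c3[1] - a[1]) - (b[1] - a[1]) * (c3[3] - a[3]),
             (b[1] - a[1]) * (c3[2] - a[2]) - (b[2] - a[2]) * (c3[1] - a[1]))
    inside <- inside &
      (p[, 1] - a[1]) * nrm[1] + (p[, 2] - a[2]) * nrm[2] +
      (p[, 3] - a[3]) * nrm[3] <= 0
    if (!any(inside)) break
  }
  mean(inside) * prod(hi - lo)
}

# dense surface+interior cloud of a cluster (volumetric sampling mode)
solid_cluster_cloud <- function(cluster, n_surface = 300L,
                                n_interior = 250L, seed = 1L) {
  sample_bunch_point_cloud(cluster, points_per_berry = n_surface,
                           interior_points_per_berry = n_interior,
                           sensor_noise_sd_cm = 0, seed = seed)$cloud$points
}
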