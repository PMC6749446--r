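#' Axis-aligned box mesh
#'
#' Watertight 12-triangle box, handy as a geometry fixture.
#'
#' @param lo,hi length-3 box corners.
#' @return A watertight `tri_mesh`.
#' @export
make_box_mesh <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # vertex order: (x fast, then y, then z); faces with outward winding
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = lo
    c(5, 6, 7), c(6, 8, 7),   # z = hi
    c(1, 2, 5), c(2, 6, 5),   # y = lo
    c(3, 7, 4), c(4, 7, 8),   # y = hi
    c(1, 5, 3), c(3, 5, 7),   # x = lo
    c(2, 4, 6), c(4, 8, 6))   # x = hi
  tri_mesh(v, f)
}

#' Regular tetrahedron-corner mesh on given vertices
#'
#' @param vertices 4 x 3 matrix of tetrahedron corners.
#' @return A watertight `tri_mesh` of the 4 faces.
#' @export
make_tetrahedron_mesh <- function(vertices = rbind(c(0, 0, 0), c(1, 0, 0),
                                                   c(0, 1, 0), c(0, 0, 1))) {
  tri_mesh(vertices, rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
}

#' Subdivided icosphere mesh
#'
#' Icosahedron subdivided `subdivisions` times with vertices projected
#' onto the sphere; watertight by construction.
#'
#' @param radius sphere radius.
#' @param subdivisions number of 4-way triangle subdivisions (>= 0).
#' @param center length-3 sphere centre.
#' @return A watertight `tri_mesh`.
#' @export
make_icosphere <- function(radius = 1, subdivisions = 3L,
                           center = c(0, 0, 0)) {
  stop_if_not_positive(radius, "radius")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env()
    nv <- nrow(v)
    vlist <- lapply(seq_len(nv), function(i) v[i, ])
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- get0(key, envir = edge_mid)
      if (!is.null(hit)) return(hit)
      m <- (vlist[[a]] + vlist[[b]]) / 2
      m <- m / sqrt(sum(m^2))
      vlist[[length(vlist) + 1]] <<- m
      id <- length(vlist)
      assign(key, id, envir = edge_mid)
      id
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc),
                  c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  v <- v * radius
  v <- sweep(v, 2, center, `+`)
  tri_mesh(v, f)
}

#' Rigidly transform a mesh or point matrix
#'
#' @param x `tri_mesh`, `bunch_point_cloud` or n x 3 matrix.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 offset.
#' @return Transformed object of the same type.
#' @export
rigid_transform <- function(x, rotation = diag(3),
                            translation = c(0, 0, 0)) {
  move <- function(p) sweep(p %*% t(rotation), 2, translation, `+`)
  if (inherits(x, "tri_mesh")) return(tri_mesh(move(x$vertices), x$faces))
  if (inherits(x, "bunch_point_cloud"))
    return(bunch_point_cloud(move(x$points), x$colours, x$label))
  move(as_point_matrix(x))
}

#' Random rotation matrix
#'
#' QR-based uniform random rotation, for invariance checks.
#'
#' @param seed integer seed.
#' @return A 3 x 3 rotation matrix with determinant +1.
#' @export
random_rotation <- function(seed = 1L) {
  with_rng_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}
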