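#' Write a point cloud to PLY
#'
#' ASCII or binary little-endian PLY with `x y z red green blue`
#' vertex properties (float coordinates, uchar colours).
#'
#' @param cloud a `bunch_point_cloud`.
#' @param path output file.
#' @param binary write binary little-endian instead of ASCII.
#' @export
write_ply <- function(cloud, path, binary = FALSE) {
  stopifnot(inherits(cloud, "bunch_point_cloud"))
  n <- nrow(cloud$points)
  header <- c("ply",
              sprintf("format %s 1.0",
                      if (binary) "binary_little_endian" else "ascii"),
              sprintf("element vertex %d", n),
              "property float x", "property float y", "property float z",
              "property uchar red", "property uchar green",
              "property uchar blue", "end_header")
  if (!binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    if (n > 0) {
      lines <- sprintf("%.6g %.6g %.6g %d %d %d",
                       cloud$points[, 1], cloud$points[, 2],
                       cloud$points[, 3],
                       as.integer(round(cloud$colours[, 1])),
                       as.integer(round(cloud$colours[, 2])),
                       as.integer(round(cloud$colours[, 3])))
      writeLines(lines, con)
    }
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  if (n > 0) {
    # interleave per-record bytes: 3 float32 + 3 uchar
    fbytes <- writeBin(as.numeric(t(cloud$points)), raw(), size = 4,
                       endian = "little")
    fmat <- matrix(fbytes, nrow = 12)
    cmat <- matrix(as.raw(round(t(cloud$colours))), nrow = 3)
    writeBin(as.vector(rbind(fmat, cmat)), con)
  }
  invisible(path)
}

#' Read a PLY point cloud
#'
#' Supports ASCII and binary little-endian PLY with float32/float64
#' coordinates and optional uchar red/green/blue properties.
#'
#' @param path PLY file.
#' @return A `bunch_point_cloud`.
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("malformed PLY: no end_header")
    header <- c(header, line)
    if (line == "end_header") break
  }
  if (header[1] != "ply") stop("not a PLY file")
  fmt <- sub("^format ([a-z_]+).*", "\\1", grep("^format", header,
                                                value = TRUE)[1])
  n <- as.integer(sub("^element vertex (\\d+).*", "\\1",
                      grep("^element vertex", header, value = TRUE)[1]))
  props <- grep("^property", header, value = TRUE)
  pname <- sub("^property +\\S+ +", "", props)
  ptype <- sub("^property +(\\S+) +.*", "\\1", props)
  if (fmt == "ascii") {
    vals <- scan(con, what = numeric(), n = n * length(pname), quiet = TRUE)
    m <- matrix(vals, ncol = length(pname), byrow = TRUE)
  } else if (fmt == "binary_little_endian") {
    sizes <- ifelse(ptype %in% c("float", "float32"), 4L,
             ifelse(ptype %in% c("double", "float64"), 8L,
             ifelse(ptype %in% c("uchar", "uint8", "char", "int8"), 1L,
                    NA_integer_)))
    if (any(is.na(sizes))) stop("unsupported PLY property type")
    rec <- sum(sizes)
    raws <- readBin(con, raw(), n = n * rec)
    rawmat <- matrix(raws, nrow = rec)
    m <- matrix(0, n, length(pname))
    off <- 0L
    for (j in seq_along(pname)) {
      b <- rawmat[(off + 1):(off + sizes[j]), , drop = FALSE]
      m[, j] <- switch(as.character(sizes[j]),
        "4" = readBin(as.vector(b), numeric(), n = n, size = 4,
                      endian = "little"),
        "8" = readBin(as.vector(b), numeric(), n = n, size = 8,
                      endian = "little"),
        "1" = as.numeric(readBin(as.vector(b), integer(), n = n, size = 1,
                                 signed = FALSE)))
      off <- off + sizes[j]
    }
  } else stop("unsupported PLY format: ", fmt)
  colnames(m) <- pname
  pts <- m[, c("x", "y", "z"), drop = FALSE]
  cols <- if (all(c("red", "green", "blue") %in% pname))
    m[, c("red", "green", "blue"), drop = FALSE] else NULL
  bunch_point_cloud(pts, cols)
}

#' Write a triangle mesh to STL
#'
#' Binary STL by default (80-byte header, float32 triangles); set
#' `ascii = TRUE` for the text variant.
#'
#' @param mesh a `tri_mesh`.
#' @param path output file.
#' @param ascii write ASCII STL.
#' @export
write_stl <- function(mesh, path, ascii = FALSE) {
  stopifnot(inherits(mesh, "tri_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  p0 <- v[f[, 1], , drop = FALSE]
  p1 <- v[f[, 2], , drop = FALSE]
  p2 <- v[f[, 3], , drop = FALSE]
  u <- p1 - p0; w <- p2 - p0
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %.6e %.6e %.6e", nrm[i, 1], nrm[i, 2],
                nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.6e %.6e %.6e", p0[i, 1], p0[i, 2], p0[i, 3]),
        sprintf("      vertex %.6e %.6e %.6e", p1[i, 1], p1[i, 2], p1[i, 3]),
        sprintf("      vertex %.6e %.6e %.6e", p2[i, 1], p2[i, 2], p2[i, 3]),
        "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80)), con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  tri <- cbind(nrm, p0, p1, p2)  # 12 floats per triangle
  fbytes <- writeBin(as.numeric(t(tri)), raw(), size = 4, endian = "little")
  fmat <- matrix(fbytes, nrow = 48)
  attr_bytes <- matrix(as.raw(0L), nrow = 2, ncol = nrow(f))
  writeBin(as.vector(rbind(fmat, attr_bytes)), con)
  invisible(path)
}

#' Read an STL triangle mesh
#'
#' Reads binary or ASCII STL; duplicated corner vertices are welded by
#' exact coordinate match.
#'
#' @param path STL file.
#' @return A `tri_mesh`.
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, raw(), n = 80)
  probe <- rawToChar(head[head != as.raw(0)][1:min(5, sum(head != as.raw(0)))])
  close(con)
  if (startsWith(probe, "solid")) {
    # could still be binary with a "solid" header; check facet keyword
    txt <- tryCatch(readLines(path, warn = FALSE), error = function(e) NULL)
    if (!is.null(txt) && any(grepl("facet normal", txt))) {
      vl <- grep("^\\s*vertex", txt, value = TRUE)
      nums <- lapply(strsplit(trimws(vl), "\\s+"), function(p)
        as.numeric(p[2:4]))
      verts <- do.call(rbind, nums)
      return(weld_mesh(verts))
    }
  }
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, raw(), n = 80)
  nf <- readBin(con, integer(), n = 1, size = 4, endian = "little")
  raws <- readBin(con, raw(), n = nf * 50)
  rawmat <- matrix(raws, nrow = 50)
  fl <- readBin(as.vector(rawmat[1:48, , drop = FALSE]), numeric(),
                n = nf * 12, size = 4, endian = "little")
  tri <- matrix(fl, ncol = 12, byrow = TRUE)
  verts <- matrix(0, 3 * nf, 3)
  verts[seq(1, 3 * nf, by = 3), ] <- tri[, 4:6, drop = FALSE]
  verts[seq(2, 3 * nf, by = 3), ] <- tri[, 7:9, drop = FALSE]
  verts[seq(3, 3 * nf, by = 3), ] <- tri[, 10:12, drop = FALSE]
  weld_mesh(verts)
}

# verts are consecutive triangle corners (3 rows per face); weld exact
# duplicates into shared vertices
weld_mesh <- function(verts) {
  key <- paste(verts[, 1], verts[, 2], verts[, 3])
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  tri_mesh(verts[uk, , drop = FALSE], faces)
}

#' Write an RGB scene (or mask) as PNG
#'
#' Scenes are written as 8-bit RGB; logical masks as 0/255 greyscale.
#' Out-of-ROI `NA` pixels are written as black.
#'
#' @param x an `rgb_scene`, an image array, or a logical mask matrix.
#' @param path output PNG path.
#' @export
write_image_png <- function(x, path) {
  if (inherits(x, "rgb_scene")) x <- x$image
  if (is.logical(x)) x <- array(as.numeric(x), dim = c(dim(x), 1))
  x[is.na(x)] <- 0
  png::writePNG(x, target = path)
  invisible(path)
}

#' Read a PNG image as an RGB array
#'
#' @param path PNG file.
#' @param pixels_per_cm optional known scale; when given, the result is
#'   an `rgb_scene`.
#' @return An array (values on `[0,1]`) or `rgb_scene`.
#' @export
read_image_png <- function(path, pixels_per_cm = NULL) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  if (is.null(pixels_per_cm)) return(img)
  structure(list(image = img, pixels_per_cm = pixels_per_cm,
                 ruler_px = NA_real_, ruler_cm = NA_real_),
            class = "rgb_scene")
}

#' Write a parameter sidecar in YAML
#'
#' Records seeds and generator/analysis parameters next to generated
#' artefacts.
#'
#' @param params named list.
#' @param path output YAML path.
#' @export
write_sidecar_yaml <- function(params, path) {
  yaml::write_yaml(params, path)
  invisible(path)
}

#' Serialize HSV thresholds to YAML
#' @param thresholds an [hsv_thresholds()] object.
#' @param path output YAML path.
#' @export
write_thresholds_yaml <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "hsv_thresholds"))
  yaml::write_yaml(unclass(thresholds), path)
  invisible(path)
}

#' Read HSV thresholds from YAML
#' @param path YAML path written by [write_thresholds_yaml()].
#' @return An [hsv_thresholds()] object.
#' @export
read_thresholds_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  hsv_thresholds(x$hue_lo, x$hue_hi, x$sat_lo, x$sat_hi, x$val_lo, x$val_hi)
}
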