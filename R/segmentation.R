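#' Scale calibration from an in-frame reference length
#'
#' Converts the pixel length of a reference marker of known physical
#' length into the image scale and the physical area of one pixel (the
#' calibration value, cm^2 per pixel).
#'
#' @param ref_length_px marker length in pixels (> 0).
#' @param ref_length_cm marker length in cm (> 0).
#' @return Object of class `scale_calibration` with `pixels_per_cm` and
#'   `calibration_value_cm2_per_px = (1 / pixels_per_cm)^2`.
#' @export
calibrate_scale <- function(ref_length_px, ref_length_cm) {
  stop_if_not_positive(ref_length_px, "ref_length_px")
  stop_if_not_positive(ref_length_cm, "ref_length_cm")
  ppcm <- ref_length_px / ref_length_cm
  structure(list(pixels_per_cm = ppcm,
                 calibration_value_cm2_per_px = (1 / ppcm)^2),
            class = "scale_calibration")
}

#' @export
print.scale_calibration <- function(x, ...) {
  cat(sprintf("<scale: %.3f px/cm, %.6g cm^2/px>\n",
              x$pixels_per_cm, x$calibration_value_cm2_per_px))
  invisible(x)
}

scene_image <- function(image) {
  if (inherits(image, "rgb_scene")) image$image
  else if (is.array(image) && length(dim(image)) == 3 &&
           dim(image)[3] == 3) image
  else stop("expected an rgb_scene or an nr x nc x 3 array")
}

# do any two non-adjacent polygon edges properly intersect?
polygon_self_intersects <- function(poly) {
  m <- nrow(poly)
  seg <- cbind(poly, poly[c(2:m, 1), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(m - 2)) {
    jmax <- if (i == 1) m - 1 else m
    for (j in (i + 2):jmax) {
      p <- seg[i, ]; q <- seg[j, ]
      d1 <- cross(p[1], p[2], p[3], p[4], q[1], q[2])
      d2 <- cross(p[1], p[2], p[3], p[4], q[3], q[4])
      d3 <- cross(q[1], q[2], q[3], q[4], p[1], p[2])
      d4 <- cross(q[1], q[2], q[3], q[4], p[3], p[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

# even-odd point-in-polygon test for pixel centres
points_in_polygon <- function(px, py, poly) {
  inside <- rep(FALSE, length(px))
  m <- nrow(poly)
  j <- m
  for (i in seq_len(m)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      inside <- xor(inside, crosses & px < xint)
    }
    j <- i
  }
  inside
}

#' Mask a region of interest
#'
#' Pixels outside the polygon are set to `NA` (the ROI sentinel) and are
#' excluded from all downstream pixel counts. Omitting the polygon keeps
#' the full frame.
#'
#' @param image an `rgb_scene` or `nr x nc x 3` array.
#' @param polygon m x 2 matrix of (x, y) vertices in pixel units, with x
#'   along columns and y along rows (y = 0 at the top edge). Must be a
#'   simple polygon with at least 3 vertices.
#' @return Same type as the input with out-of-ROI pixels set to `NA`.
#' @export
mask_roi <- function(image, polygon = NULL) {
  img <- scene_image(image)
  if (is.null(polygon)) return(image)
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3 || ncol(polygon) != 2)
    stop("polygon needs at least 3 (x, y) vertices")
  if (polygon_self_intersects(polygon)) stop("polygon is self-intersecting")
  nr <- dim(img)[1]; nc <- dim(img)[2]
  px <- rep(seq_len(nc) - 0.5, each = nr)
  py <- rep(seq_len(nr) - 0.5, times = nc)
  inside <- matrix(points_in_polygon(px, py, polygon), nr, nc)
  if (!any(inside)) warning("ROI polygon selects no pixels")
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[!inside] <- NA_real_
    img[, , ch] <- pl
  }
  if (inherits(image, "rgb_scene")) {
    image$image <- img
    image
  } else img
}

image_hsv <- function(img) {
  nr <- dim(img)[1]; nc <- dim(img)[2]
  rgbm <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                as.vector(img[, , 3]))
  ok <- !is.na(rgbm[1, ])
  hsv <- matrix(NA_real_, 3, nr * nc)
  if (any(ok)) hsv[, ok] <- rgb2hsv(rgbm[, ok, drop = FALSE],
                                    maxColorValue = 1)
  list(h = matrix(hsv[1, ], nr, nc), s = matrix(hsv[2, ], nr, nc),
       v = matrix(hsv[3, ], nr, nc))
}

#' HSV threshold set
#'
#' @param hue_lo,hue_hi hue bounds on `[0, 1)`; the interval is read
#'   circularly when `hue_lo > hue_hi`.
#' @param sat_lo,sat_hi,val_lo,val_hi saturation/value bounds on `[0, 1]`
#'   with `lo <= hi`.
#' @return Object of class `hsv_thresholds`.
#' @export
hsv_thresholds <- function(hue_lo, hue_hi, sat_lo, sat_hi, val_lo, val_hi) {
  if (sat_lo > sat_hi || val_lo > val_hi)
    stop("saturation/value bounds must satisfy lo <= hi")
  vals <- c(hue_lo, hue_hi, sat_lo, sat_hi, val_lo, val_hi)
  if (any(vals < 0) || any(vals > 1)) stop("thresholds must lie in [0, 1]")
  structure(list(hue_lo = hue_lo, hue_hi = hue_hi, sat_lo = sat_lo,
                 sat_hi = sat_hi, val_lo = val_lo, val_hi = val_hi),
            class = "hsv_thresholds")
}

#' @export
print.hsv_thresholds <- function(x, ...) {
  cat(sprintf("<hsv_thresholds: H [%.3f, %.3f]%s S [%.3f, %.3f] V [%.3f, %.3f]>\n",
              x$hue_lo, x$hue_hi,
              if (x$hue_lo > x$hue_hi) " (wrapped)" else "",
              x$sat_lo, x$sat_hi, x$val_lo, x$val_hi))
  invisible(x)
}

circular_hue_envelope <- function(h, quantile) {
  h <- sort(h %% 1)
  n <- length(h)
  if (n == 1) return(c(h, h))
  gaps <- c(diff(h), h[1] + 1 - h[n])
  cut <- which.max(gaps)
  # rotate so the largest empty arc wraps around the linearized ends
  origin <- if (cut == n) h[1] else h[cut + 1]
  h2 <- (h - origin) %% 1
  qs <- stats::quantile(h2, c(quantile, 1 - quantile), names = FALSE)
  (qs + origin) %% 1
}

#' Fit HSV thresholds from labelled training images
#'
#' Pools the H, S, V values of grape-labelled pixels over the training
#' set and returns the per-channel `[quantile, 1 - quantile]` envelope;
#' the hue envelope is computed circularly (the largest empty hue arc is
#' placed at the wrap point before taking quantiles). This replaces an
#' interactive colour-threshold selection with a reproducible rule.
#'
#' Because the three channel envelopes are intersected by
#' [segment_scene()], the expected joint grape-pixel retention is about
#' `(1 - 2 * quantile)^3`; the default 0.002 keeps it near 99%.
#'
#' @param training list of `list(image =, mask =)` pairs, where `mask` is
#'   a logical matrix marking grape pixels.
#' @param quantile tail fraction clipped per channel, in `[0, 0.5)`;
#'   0 gives the min/max envelope.
#' @return An [hsv_thresholds()] object.
#' @export
fit_thresholds <- function(training, quantile = 0.002) {
  if (length(training) == 0) stop("training set is empty")
  if (quantile < 0 || quantile >= 0.5) stop("quantile must be in [0, 0.5)")
  hs <- ss <- vs <- list()
  for (i in seq_along(training)) {
    img <- scene_image(training[[i]]$image)
    mask <- training[[i]]$mask
    if (is.null(mask) || !any(mask))
      stop("training image ", i, " has no grape pixels in its mask")
    hsv <- image_hsv(img)
    hs[[i]] <- hsv$h[mask]
    ss[[i]] <- hsv$s[mask]
    vs[[i]] <- hsv$v[mask]
  }
  h <- unlist(hs); s <- unlist(ss); v <- unlist(vs)
  keep <- !is.na(h)
  h <- h[keep]; s <- s[keep]; v <- v[keep]
  if (length(h) == 0) stop("no usable grape pixels in the training set")
  he <- circular_hue_envelope(h, quantile)
  se <- stats::quantile(s, c(quantile, 1 - quantile), names = FALSE)
  ve <- stats::quantile(v, c(quantile, 1 - quantile), names = FALSE)
  hsv_thresholds(he[1], he[2], se[1], se[2], ve[1], ve[2])
}

hue_in_interval <- function(h, lo, hi) {
  if (lo <= hi) h >= lo & h <= hi else h >= lo | h <= hi
}

#' Segment grape pixels by HSV thresholding
#'
#' Marks pixels whose hue, saturation and value all fall within the
#' thresholds (hue circularly), then converts the positive-pixel count
#' to a physical area with the calibration value. `NA` (out-of-ROI)
#' pixels are never positive.
#'
#' @param image an `rgb_scene` or array (possibly ROI-masked).
#' @param thresholds an [hsv_thresholds()] object.
#' @param calibration a [calibrate_scale()] object.
#' @return List with `mask` (logical matrix), `n_pixels` and `area_cm2`.
#' @export
segment_scene <- function(image, thresholds, calibration) {
  stopifnot(inherits(thresholds, "hsv_thresholds"),
            inherits(calibration, "scale_calibration"))
  img <- scene_image(image)
  hsv <- image_hsv(img)
  mask <- hue_in_interval(hsv$h, thresholds$hue_lo, thresholds$hue_hi) &
    hsv$s >= thresholds$sat_lo & hsv$s <= thresholds$sat_hi &
    hsv$v >= thresholds$val_lo & hsv$v <= thresholds$val_hi
  mask[is.na(mask)] <- FALSE
  n <- sum(mask)
  if (n == 0) warning("empty segmentation: no pixels matched the thresholds")
  list(mask = mask, n_pixels = n,
       area_cm2 = n * calibration$calibration_value_cm2_per_px)
}

#' Total bunch area per vine
#'
#' Mean of the east- and west-facing side areas, in cm^2.
#'
#' @param area_east_cm2,area_west_cm2 non-negative side areas.
#' @return `(Ae + Aw) / 2`.
#' @export
tbav <- function(area_east_cm2, area_west_cm2) {
  if (any(area_east_cm2 < 0) || any(area_west_cm2 < 0))
    stop("areas must be non-negative")
  (area_east_cm2 + area_west_cm2) / 2
}

#' Evaluate a segmentation against ground truth
#'
#' Confusion counts with grape as the positive class, plus
#' `f1 = 2 tp / (2 tp + fp + fn)` and `accuracy = (tp + tn) / total`.
#' When truth and prediction are both entirely negative the F1 score is
#' defined as 1 (perfect agreement on an empty positive class).
#'
#' @param predicted,truth congruent logical matrices.
#' @return List with `counts` (class `confusion_counts`: tp, fp, fn,
#'   tn), `f1` and `accuracy`.
#' @export
evaluate_segmentation <- function(predicted, truth) {
  if (!identical(dim(predicted), dim(truth)))
    stop("predicted and truth masks must have identical shape")
  tp <- sum(predicted & truth)
  fp <- sum(predicted & !truth)
  fn <- sum(!predicted & truth)
  tn <- sum(!predicted & !truth)
  f1 <- if (2 * tp + fp + fn == 0) 1.0 else 2 * tp / (2 * tp + fp + fn)
  list(counts = structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
                          class = "confusion_counts"),
       f1 = f1, accuracy = (tp + tn) / (tp + fp + fn + tn))
}
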