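test_that("scale calibration follows the reference-length arithmetic", {
  cal <- calibrate_scale(200, 10)
  expect_identical(cal$pixels_per_cm, 20)
  expect_equal(cal$calibration_value_cm2_per_px, 0.0025)
  expect_identical(calibrate_scale(1, 1)$calibration_value_cm2_per_px, 1.0)
  expect_error(calibrate_scale(0, 10), "positive")
  expect_error(calibrate_scale(10, -1), "positive")
})

test_that("ROI masking rasterizes polygons exactly", {
  img <- array(runif(200 * 150 * 3), dim = c(150, 200, 3))
  expect_identical(mask_roi(img, NULL), img)
  # frame-covering polygon changes nothing
  full <- mask_roi(img, rbind(c(-1, -1), c(201, -1), c(201, 151), c(-1, 151)))
  expect_identical(full, img)
  # axis-aligned 100 x 50 rectangle -> 5000 in-ROI pixels
  rect <- mask_roi(img, rbind(c(0, 0), c(100, 0), c(100, 50), c(0, 50)))
  expect_identical(sum(!is.na(rect[, , 1])), 5000L)
  # degenerate zero-area polygon -> empty ROI and downstream area 0
  expect_warning(deg <- mask_roi(img, rbind(c(5, 5), c(5, 5), c(5, 5))),
                 "no pixels")
  expect_true(all(is.na(deg[, , 1])))
  thr <- hsv_thresholds(0, 1, 0, 1, 0, 1)
  cal <- calibrate_scale(10, 1)
  expect_warning(seg <- segment_scene(deg, thr, cal), "empty segmentation")
  expect_identical(seg$area_cm2, 0)
  # bow-tie polygon is rejected
  expect_error(mask_roi(img, rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))),
               "self-intersecting")
})

test_that("threshold fitting produces containing envelopes", {
  # degenerate: all grape pixels share one colour -> lo == hi per channel
  img <- array(0, dim = c(20, 20, 3))
  img[, , 1] <- 0.4; img[, , 2] <- 0.1; img[, , 3] <- 0.5  # fixed HSV
  mask <- matrix(TRUE, 20, 20)
  thr <- fit_thresholds(list(list(image = img, mask = mask)), quantile = 0.1)
  expect_equal(thr$sat_lo, thr$sat_hi)
  expect_equal(thr$val_lo, thr$val_hi)
  expect_equal(thr$hue_lo, thr$hue_hi, tolerance = 1e-12)
  expect_error(fit_thresholds(list(list(image = img,
                                        mask = matrix(FALSE, 20, 20)))),
               "no grape pixels")
  # quantile 0: every training grape pixel is classified positive
  cl <- generate_bunch_cluster(10, 0.6, seed = 101)
  sc <- render_bunch_image(cl, seed = 102)
  thr0 <- fit_thresholds(list(list(image = sc$scene,
                                   mask = sc$truth$true_mask)),
                         quantile = 0)
  cal <- calibrate_scale(sc$scene$ruler_px, sc$scene$ruler_cm)
  seg <- segment_scene(sc$scene, thr0, cal)
  expect_true(all(seg$mask[sc$truth$true_mask]))
})

test_that("training recall tracks the joint channel retention", {
  scenes <- lapply(1:5, function(s)
    render_bunch_image(generate_bunch_cluster(12, 0.6, seed = 110 + s),
                       seed = 120 + s))
  training <- lapply(scenes, function(sc)
    list(image = sc$scene, mask = sc$truth$true_mask))
  cal <- calibrate_scale(scenes[[1]]$scene$ruler_px, 10)
  recall_at <- function(q) {
    thr <- fit_thresholds(training, quantile = q)
    mean(vapply(scenes, function(sc) {
      seg <- segment_scene(sc$scene, thr, cal)
      sum(seg$mask & sc$truth$true_mask) / sum(sc$truth$true_mask)
    }, 0))
  }
  # intersecting three [q, 1-q] envelopes retains about (1-2q)^3
  r01 <- recall_at(0.01)
  expect_gte(r01, 0.92)
  expect_lt(abs(r01 - 0.98^3), 0.02)
  # the package default keeps recall near 99%
  expect_gte(recall_at(0.002), 0.98)
})

test_that("segmentation area follows the pixel-count calibration", {
  # 4000 positive pixels at 0.0025 cm^2/px -> 10 cm^2
  img <- array(0, dim = c(100, 100, 3))
  sel <- matrix(FALSE, 100, 100)
  sel[11:50, 1:100] <- TRUE              # 4000 pixels
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[sel] <- c(0.5, 0.1, 0.6)[ch]
    img[, , ch] <- pl
  }
  thr <- fit_thresholds(list(list(image = img, mask = sel)), 0)
  seg <- segment_scene(img, thr, calibrate_scale(20, 1))
  expect_identical(seg$n_pixels, 4000L)
  expect_equal(seg$area_cm2, 10.0)
  # all-background image -> area 0 with a warning
  bg <- array(rep(c(0.1, 0.7, 0.2), each = 50 * 50), dim = c(50, 50, 3))
  expect_warning(seg0 <- segment_scene(bg, thr, calibrate_scale(20, 1)),
                 "empty segmentation")
  expect_identical(seg0$area_cm2, 0)
})

test_that("fitted thresholds recover unoccluded scene area within 3%", {
  cl <- generate_bunch_cluster(14, 0.6, seed = 131)
  sc <- render_bunch_image(cl, seed = 132)
  thr <- fit_thresholds(list(list(image = sc$scene,
                                  mask = sc$truth$true_mask)))
  cal <- calibrate_scale(sc$scene$ruler_px, sc$scene$ruler_cm)
  seg <- segment_scene(sc$scene, thr, cal)
  expect_lt(abs(seg$area_cm2 - sc$truth$true_area_cm2) /
              sc$truth$true_area_cm2, 0.03)
})

test_that("segmented area is invariant to translation and benign ROI growth", {
  cl <- generate_bunch_cluster(10, 0.6, seed = 141)
  sc <- render_bunch_image(cl, seed = 142)
  thr <- fit_thresholds(list(list(image = sc$scene,
                                  mask = sc$truth$true_mask)), 0.01)
  cal <- calibrate_scale(sc$scene$ruler_px, sc$scene$ruler_cm)
  base <- segment_scene(sc$scene, thr, cal)
  # translate the frame by padding with background-coloured border
  img <- sc$scene$image
  pad <- array(0, dim = dim(img) + c(8, 8, 0))
  pad[, , 1] <- 0.2; pad[, , 2] <- 0.55; pad[, , 3] <- 0.25
  pad[8 + seq_len(nrow(img)), 8 + seq_len(ncol(img)), ] <- img
  shifted <- segment_scene(pad, thr, cal)
  expect_identical(shifted$n_pixels, base$n_pixels)
  # ROI enlargement that adds only background pixels
  nr <- nrow(img); ncl <- ncol(img)
  tight <- segment_scene(mask_roi(sc$scene, rbind(c(0, 0), c(ncl, 0),
                                                  c(ncl, nr), c(0, nr))),
                         thr, cal)
  expect_identical(tight$n_pixels, base$n_pixels)
})

test_that("widening any threshold channel never removes a positive pixel", {
  cl <- generate_bunch_cluster(10, 0.6, seed = 151)
  sc <- render_bunch_image(cl, seed = 152)
  thr <- fit_thresholds(list(list(image = sc$scene,
                                  mask = sc$truth$true_mask)), 0.05)
  cal <- calibrate_scale(sc$scene$ruler_px, sc$scene$ruler_cm)
  base <- segment_scene(sc$scene, thr, cal)
  widen <- list(
    hsv_thresholds(max(0, thr$hue_lo - 0.05), min(1, thr$hue_hi + 0.05),
                   thr$sat_lo, thr$sat_hi, thr$val_lo, thr$val_hi),
    hsv_thresholds(thr$hue_lo, thr$hue_hi, max(0, thr$sat_lo - 0.2),
                   min(1, thr$sat_hi + 0.2), thr$val_lo, thr$val_hi),
    hsv_thresholds(thr$hue_lo, thr$hue_hi, thr$sat_lo, thr$sat_hi,
                   max(0, thr$val_lo - 0.2), min(1, thr$val_hi + 0.2)))
  for (w in widen) {
    seg <- segment_scene(sc$scene, w, cal)
    expect_true(all(seg$mask[base$mask]))
  }
})

test_that("hue thresholds wrap circularly around 0", {
  # reds straddling hue 0: interval [0.95, 0.05]
  thr <- hsv_thresholds(0.95, 0.05, 0, 1, 0, 1)
  img <- array(0, dim = c(1, 3, 3))
  img[1, 1, ] <- c(1, 0.02, 0.02)   # hue ~ 0
  img[1, 2, ] <- c(1, 0, 0.3)       # hue ~ 0.95
  img[1, 3, ] <- c(0, 1, 0)         # green
  seg <- segment_scene(img, thr, calibrate_scale(1, 1))
  expect_identical(as.vector(seg$mask), c(TRUE, TRUE, FALSE))
})

test_that("tbav averages sides, is symmetric, and validates input", {
  expect_identical(tbav(100, 140), 120)
  expect_identical(tbav(0, 0), 0)
  x <- runif(1, 1, 500)
  expect_identical(tbav(x, x), x)
  expect_identical(tbav(3, 9), tbav(9, 3))
  expect_error(tbav(-0.1, 5), "non-negative")
})

test_that("confusion metrics match their closed forms", {
  pred <- matrix(FALSE, 100, 10)
  truth <- matrix(FALSE, 100, 10)
  pred[1:100] <- c(rep(TRUE, 90), rep(TRUE, 10), rep(FALSE, 0))
  # build exact counts: tp=90, fp=10, fn=10, tn=890
  pred <- matrix(FALSE, 100, 10); truth <- matrix(FALSE, 100, 10)
  truth[1:100] <- TRUE            # 100 true positives available
  pred[1:90] <- TRUE              # 90 of them predicted
  pred[101:110] <- TRUE           # 10 false positives
  ev <- evaluate_segmentation(pred, truth)
  expect_identical(ev$counts$tp, 90L)
  expect_identical(ev$counts$fp, 10L)
  expect_identical(ev$counts$fn, 10L)
  expect_identical(ev$counts$tn, 890L)
  expect_equal(ev$f1, 0.9)
  expect_equal(ev$accuracy, 0.98)
  ident <- evaluate_segmentation(truth, truth)
  expect_identical(ident$f1, 1.0)
  expect_identical(ident$accuracy, 1.0)
  flipped <- evaluate_segmentation(!truth, truth)
  expect_identical(flipped$f1, 0)
  expect_identical(flipped$accuracy, 0)
  both_empty <- evaluate_segmentation(matrix(FALSE, 5, 5),
                                      matrix(FALSE, 5, 5))
  expect_identical(both_empty$f1, 1.0)
  expect_error(evaluate_segmentation(matrix(FALSE, 2, 2),
                                     matrix(FALSE, 3, 3)),
               "identical shape")
})
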