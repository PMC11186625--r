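# Photograph preprocessing: fiducials, calibration, rectification,
# segmentation and slice grouping.

make_marker_scene <- function() {
  centers <- rbind(c(100, 100), c(100, 700), c(500, 700), c(500, 100))
  photo <- matrix(0.1, 600, 800)
  tpl <- list()
  for (i in 1:4) {
    mi <- blob_marker(i + 10)
    tpl[[i]] <- list(image = mi)
    photo[centers[i, 1] - 32 + 1:64, centers[i, 2] - 32 + 1:64] <- mi
  }
  list(photo = photo, centers = centers + 0.5, templates = tpl)
}

test_that("fiducial markers are localized to sub-pixel accuracy", {
  sc <- make_marker_scene()
  geom <- list(width = 120, height = 80)
  fs <- detect_fiducials(sc$photo, sc$templates, geom)
  err <- sqrt(rowSums((fs$points - sc$centers)^2))
  expect_true(all(err < 2))
  expect_true(all(fs$confidence >= 4))

  # the same scene rotated 10 degrees about the image centre
  ang <- 10 * pi / 180
  ctr <- c((600 + 1) / 2, (800 + 1) / 2)
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  g <- expand.grid(r = 1:600, c = 1:800)
  src <- t(solve(R) %*% t(as.matrix(g) - rep(ctr, each = nrow(g)))) +
    rep(ctr, each = nrow(g))
  rot <- matrix(photorecon:::interp2(sc$photo, src[, 2], src[, 1])$v, 600, 800)
  fs2 <- detect_fiducials(rot, sc$templates, geom)
  expected <- t(R %*% (t(sc$centers) - ctr) + ctr)
  err2 <- sqrt(rowSums((fs2$points - expected)^2))
  expect_true(all(err2 < 2))

  # a blank photograph has no features
  expect_error(detect_fiducials(matrix(0, 200, 200), sc$templates, geom),
               "MarkerNotFound")
})

test_that("calibration fits recover scale and perspective exactly", {
  # axis-aligned square: 100 px sides for a 10 mm physical square
  pts4 <- rbind(c(0, 0), c(0, 100), c(100, 100), c(100, 0)) + 50
  fs <- fiducial_set(pts4, list(width = 10, height = 10))
  cal <- fit_calibration(fs)
  expect_equal(cal$mode, "full_perspective")
  expect_equal(cal$pixel_size, 0.1, tolerance = 1e-9)
  mm <- calibrate_points(cal, pts4)
  expect_equal(mm, rbind(c(0, 0), c(0, 10), c(10, 10), c(10, 0)),
               tolerance = 1e-9, ignore_attr = TRUE)

  # 2 points, 50 px apart, 5 mm known distance
  fs2 <- fiducial_set(rbind(c(10, 10), c(10, 60)), list(distance = 5))
  cal2 <- fit_calibration(fs2)
  expect_equal(cal2$mode, "scale_only")
  expect_equal(cal2$pixel_size, 0.1, tolerance = 1e-12)

  # projective warp of a 120 x 80 mm rectangle: fitted transform inverts it
  H <- rbind(c(8.2, 0.45, 60), c(-0.35, 7.9, 140), c(2e-4, -3e-4, 1))
  rect_mm <- rbind(c(0, 0), c(0, 120), c(80, 120), c(80, 0))
  px <- photorecon:::apply_homography(H, rect_mm)
  fs3 <- fiducial_set(px, list(width = 120, height = 80))
  cal3 <- fit_calibration(fs3)
  held_out <- withr::with_seed(5, cbind(runif(20, 0, 80), runif(20, 0, 120)))
  px_h <- photorecon:::apply_homography(H, held_out)
  back <- calibrate_points(cal3, px_h)
  expect_lt(max(sqrt(rowSums((back - held_out)^2))), 1e-6)

  # degenerate geometry
  expect_error(fit_calibration(
    fiducial_set(rbind(c(0, 0), c(0, 50), c(0, 100)),
                 list(arm1 = 5, arm2 = 10))), "DegenerateGeometry")
})

test_that("rectification resamples onto a regular physical grid", {
  # identity calibration at native pixel size: grayscale passthrough
  img <- withr::with_seed(6, matrix(runif(80 * 60), 60, 80))
  cal <- planar_calibration(diag(3), 1, "scale_only")
  rp <- rectify(raw_photo(img), cal, 1)
  expect_equal(rp$pixels[1:60, 1:80], img, tolerance = 1e-12)

  # doubling the pixel size on a constant image halves the dimensions
  cst <- matrix(0.7, 64, 64)
  rp2 <- rectify(raw_photo(cst), cal, 2)
  expect_true(all(abs(dim(rp2$pixels) - c(33, 33)) <= 1))
  inner <- rp2$pixels[2:31, 2:31]
  expect_equal(inner, matrix(0.7, 30, 30), tolerance = 1e-12)

  # band-limited checkerboard warped by a known homography, rectified via
  # the fitted calibration: round trip within interpolation tolerance.
  # The warped photo is built analytically (the continuous pattern sampled
  # through H^-1), so the comparison isolates the rectification error.
  pattern <- function(r, c) {
    0.5 + 0.25 * (tanh(3 * sin(pi * (r - 1) / 10)) +
                    tanh(3 * sin(pi * (c - 1) / 10))) / 2
  }
  cb <- outer(1:80, 1:80, pattern)
  Hw <- rbind(c(1.05, 0.04, 3), c(-0.03, 0.98, 5), c(1e-4, -8e-5, 1))
  g <- expand.grid(r = 1:96, c = 1:96)
  src <- photorecon:::apply_homography(solve(Hw), as.matrix(g))
  warped <- matrix(pattern(src[, 1], src[, 2]), 96, 96)
  warped[src[, 1] < 1 | src[, 1] > 80 | src[, 2] < 1 | src[, 2] > 80] <- 0
  corners_cb <- rbind(c(1, 1), c(1, 80), c(80, 80), c(80, 1))
  corners_px <- photorecon:::apply_homography(Hw, corners_cb)
  # physical rectangle: the checkerboard is 79 x 79 "mm" at 1 mm/px
  fs <- fiducial_set(corners_px, list(width = 79, height = 79))
  cal3 <- fit_calibration(fs)
  rp3 <- rectify(raw_photo(warped), cal3, 1)
  # compare on the interior of the common support; rectified pixel (1,1)
  # sits at rp3$origin_mm, and checkerboard pixel i sits at mm i - 1
  r0 <- round(1 - rp3$origin_mm[1]); c0 <- round(1 - rp3$origin_mm[2])
  got <- rp3$pixels[r0 + 5:73, c0 + 5:73]
  want <- cb[1 + 5:73, 1 + 5:73]
  expect_lt(mean(abs(got - want)), 0.02)
})

test_that("tissue segmentation applies threshold, morphology and area filter", {
  img <- matrix(0, 60, 60)
  img[10:39, 10:39] <- 200 / 255
  cp <- calibrated_photo(img, pixel_size = 1)
  m <- segment_tissue(cp, threshold = 100 / 255, min_area = 0,
                      morph_radius = 1)
  expect_equal(m$n_components, 1)
  expect_equal(sum(m$mask), 900)
  expect_equal(unname(range(m$components)), c(0, 1))

  expect_warning(segment_tissue(calibrated_photo(matrix(0, 30, 30), 1),
                                threshold = 0.5), "EmptyMask")

  # min_area removes the smaller of two blobs
  img2 <- matrix(0, 80, 80)
  img2[5:27, 5:27] <- 0.9       # 529 px
  img2[50:71, 50:71] <- 0.9     # 484 px
  cp2 <- calibrated_photo(img2, pixel_size = 1)
  m2 <- segment_tissue(cp2, threshold = 0.5, min_area = 500, morph_radius = 1)
  expect_equal(m2$n_components, 1)
  expect_true(m2$mask[15, 15] == 1 && m2$mask[60, 60] == 0)

  # segmentation is invariant to sub-threshold background noise
  noise <- withr::with_seed(7, matrix(runif(80 * 80, 0, 0.3), 80, 80))
  noise[img2 > 0] <- 0
  m3 <- segment_tissue(calibrated_photo(img2 + noise, 1), threshold = 0.5,
                       min_area = 500, morph_radius = 1)
  expect_identical(m3$mask, m2$mask)
})

test_that("components group into ordered slice records", {
  comp <- matrix(0L, 30, 30)
  comp[2:8, 2:8] <- 1L; comp[2:8, 14:20] <- 2L; comp[14:20, 2:8] <- 3L
  mask <- structure(list(mask = (comp > 0) * 1, components = comp,
                         n_components = 3L, pixel_size = 1),
                    class = "tissue_mask")
  rec <- group_components(mask, list(order = "anterior_first",
                                     slices = list(1L, 2L, 3L)))
  expect_equal(rec$slice_index, 0:2)
  expect_equal(unlist(rec$component_ids), 1:3)

  # posterior-first photographs are flipped to anterior -> posterior
  rec2 <- group_components(mask, list(order = "posterior_first",
                                      slices = list(1L, 2L, 3L)))
  expect_equal(unlist(rec2$component_ids), 3:1)

  # temporal-pole case: two components in one slice
  rec3 <- group_components(mask, list(order = "anterior_first",
                                      slices = list(c(1L, 2L), 3L)))
  expect_equal(nrow(rec3), 2)
  expect_equal(rec3$component_ids[[1]], c(1L, 2L))

  # partition property: every id exactly once
  ids <- unlist(rec3$component_ids)
  expect_equal(sort(ids), 1:3)
  expect_false(anyDuplicated(ids) > 0)

  expect_error(group_components(mask, list(order = "anterior_first",
                                           slices = list(1L, 3L))),
               "UnassignedComponent")
  expect_error(group_components(mask, list(order = "anterior_first",
                                           slices = list(c(1L, 2L), c(2L, 3L)))),
               "DuplicateAssignment")
})

test_that("grouped slices stack into a slice_stack", {
  comp <- matrix(0L, 40, 40)
  comp[5:14, 5:14] <- 1L; comp[5:14, 25:34] <- 2L; comp[25:34, 5:14] <- 3L
  photo <- calibrated_photo(0.5 * (comp > 0), pixel_size = 0.5)
  mask <- structure(list(mask = (comp > 0) * 1, components = comp,
                         n_components = 3L, pixel_size = 0.5),
                    class = "tissue_mask")
  rec <- group_components(mask, list(order = "anterior_first",
                                     slices = list(1L, c(2L, 3L))))
  st <- photo_to_stack(photo, mask, rec, thickness = 4)
  expect_s3_class(st, "slice_stack")
  expect_equal(st$n, 2)
  expect_equal(st$pixel_size, 0.5)
  expect_equal(sum(st$masks[, , 1]), 100)
  expect_equal(sum(st$masks[, , 2]), 200)
})
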