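# Preprocessing of dissection photographs: fiducial detection, planar
# calibration (pixel size + perspective), rectification, tissue
# segmentation and grouping of connected components into anatomical
# slices.
#
# Image coordinates are (row, col) with the origin at the centre of the
# top-left pixel; physical plane coordinates are mm. Photographs are
# assumed upright: the inferior-superior axis roughly vertical.

#' Raw photograph
#'
#' @param pixels numeric matrix (grayscale) or `H x W x 3` array (RGB),
#'   values in `[0, 1]` or `[0, 255]`.
#' @param metadata optional named list of provenance strings.
#' @return object of class `raw_photo`.
#' @export
raw_photo <- function(pixels, metadata = list()) {
  d <- dim(pixels)
  stopifnot(length(d) %in% c(2, 3), d[1] >= 2, d[2] >= 2)
  if (length(d) == 3 && !(d[3] %in% c(1, 3)))
    stop("channel count must be 1 or 3")
  structure(list(pixels = pixels, metadata = metadata), class = "raw_photo")
}

#' Read a photograph from PNG or TIFF
#'
#' @param path image path (PNG or TIFF; 8- or 16-bit).
#' @return a [raw_photo()].
#' @export
read_photo <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
               png = png::readPNG(path),
               tif = , tiff = {
                 if (!requireNamespace("tiff", quietly = TRUE))
                   stop("reading TIFF requires the 'tiff' package")
                 tiff::readTIFF(path)
               },
               stop("unsupported image format: ", ext))
  if (length(dim(px)) == 3 && dim(px)[3] == 4) px <- px[, , 1:3]  # drop alpha
  raw_photo(px, metadata = list(file = path))
}

#' Fiducial set
#'
#' 2-4 detected landmark coordinates plus the physical template geometry
#' that gives them meaning: a rectangle (4 points, width x height mm), two
#' ruler arms meeting at the third point (3 points, two arm lengths), or a
#' single known distance (2 points).
#'
#' @param points `k x 2` matrix of (row, col) pixel coordinates, `k` in
#'   2..4. For 4 points the order is top-left, top-right, bottom-right,
#'   bottom-left of the rectangle; for 3 points: end of arm 1, end of
#'   arm 2, corner.
#' @param template list: for 4 points `list(width, height)` (mm); for 3
#'   points `list(arm1, arm2)` (mm); for 2 points `list(distance)` (mm).
#' @param confidence optional per-point detection confidence.
#' @return object of class `fiducial_set`.
#' @export
fiducial_set <- function(points, template, confidence = NULL) {
  points <- as.matrix(points)
  k <- nrow(points)
  stopifnot(k %in% 2:4, ncol(points) == 2)
  if (anyDuplicated(round(points, 6)))
    stop("fiducial points must be pairwise distinct")
  lens <- unlist(template)
  stopifnot(all(lens > 0))
  need <- c(`2` = 1L, `3` = 2L, `4` = 2L)[as.character(k)]
  if (length(lens) < need)
    stop("template does not carry enough physical lengths for ", k, " points")
  structure(list(points = points, template = template,
                 confidence = confidence),
            class = "fiducial_set")
}

#' Detect fiducial markers by template keypoint matching
#'
#' Finds each user-supplied marker template in the photograph by
#' difference-of-Gaussian keypoint detection, orientation-normalized patch
#' descriptors and Lowe-ratio matching, then estimates the marker centre
#' from a least-squares similarity transform of the matched keypoints
#' (reducing to the match centroid when too few matches constrain it).
#'
#' @param photo a [raw_photo()] or numeric image.
#' @param templates list of marker templates, each
#'   `list(image = <matrix>, center = c(row, col))` (centre defaults to
#'   the template's middle); the list order defines the point order of
#'   the returned [fiducial_set()].
#' @param template_geometry the physical geometry list passed through to
#'   [fiducial_set()].
#' @param min_matches markers with fewer ratio-test matches raise
#'   `MarkerNotFound`.
#' @param lowe_ratio descriptor ratio-test threshold.
#' @param min_separation two markers resolving closer than this (px)
#'   raise `AmbiguousMatch`.
#' @return a [fiducial_set()] with per-marker confidence (match count).
#' @export
detect_fiducials <- function(photo, templates, template_geometry,
                             min_matches = 4L, lowe_ratio = 0.75,
                             min_separation = 10) {
  img <- as_gray(if (inherits(photo, "raw_photo")) photo$pixels else photo)
  kp_p <- kp_detect(img)
  if (nrow(kp_p) < min_matches)
    stop("MarkerNotFound: photograph yields too few keypoints")
  ori_p <- kp_orientations(img, kp_p)
  des_p <- kp_descriptors(img, kp_p, ori_p)

  centers <- matrix(NA_real_, length(templates), 2)
  conf <- integer(length(templates))
  for (m in seq_along(templates)) {
    tm <- templates[[m]]
    timg <- as_gray(tm$image)
    tcen <- if (!is.null(tm$center)) tm$center else (dim(timg) + 1) / 2
    kp_t <- kp_detect(timg)
    if (nrow(kp_t) == 0)
      stop(sprintf("MarkerNotFound: template %d has no keypoints", m))
    ori_t <- kp_orientations(timg, kp_t)
    des_t <- kp_descriptors(timg, kp_t, ori_t)
    mt <- kp_match(des_t, des_p, lowe_ratio)
    if (nrow(mt) < min_matches)
      stop(sprintf("MarkerNotFound: template %d matched only %d keypoints",
                   m, nrow(mt)))
    src <- cbind(kp_t$row[mt$i1], kp_t$col[mt$i1])
    dst <- cbind(kp_p$row[mt$i2], kp_p$col[mt$i2])
    ctr <- if (nrow(mt) >= 2) {
      ft <- fit_similarity_trimmed(src, dst)
      as.vector(ft$fit$apply(matrix(tcen, 1, 2)))
    } else {
      colMeans(dst) + (tcen - colMeans(src))
    }
    centers[m, ] <- ctr
    conf[m] <- nrow(mt)
  }
  if (length(templates) > 1) {
    dd <- as.matrix(stats::dist(centers))
    diag(dd) <- Inf
    if (min(dd) < min_separation)
      stop("AmbiguousMatch: two markers resolve to overlapping locations")
  }
  fiducial_set(centers, template_geometry, confidence = conf)
}

#' Planar calibration
#'
#' A 3x3 projective (or affine / similarity) matrix mapping raw pixel
#' coordinates (row, col) to physical plane coordinates (mm), with the
#' suggested isotropic pixel size of the rectified output.
#'
#' @param transform invertible 3x3 matrix (homogeneous, (row, col, 1) to
#'   (y_mm, x_mm, w)).
#' @param pixel_size mm/pixel of the rectified output.
#' @param mode `"full_perspective"`, `"affine"` or `"scale_only"`.
#' @return object of class `planar_calibration`.
#' @export
planar_calibration <- function(transform, pixel_size,
                               mode = c("full_perspective", "affine",
                                        "scale_only")) {
  mode <- match.arg(mode)
  stopifnot(pixel_size > 0, abs(det(transform)) > 1e-15)
  structure(list(transform = transform, pixel_size = pixel_size,
                 mode = mode),
            class = "planar_calibration")
}

#' Fit a planar calibration from a fiducial set
#'
#' The calibration mode is forced by the number of fiducials: 4 points fit
#' a full projective homography onto the physical rectangle corners, 3
#' points fit an affine transform mapping the two ruler arms onto
#' orthogonal mm axes (approximate perspective correction), and 2 points
#' give an isotropic scale only (approximate pixel-size calibration, no
#' perspective correction).
#'
#' @param fiducials a [fiducial_set()].
#' @return a [planar_calibration()].
#' @export
fit_calibration <- function(fiducials) {
  p <- fiducials$points
  k <- nrow(p)
  if (k == 2) {
    dpx <- sqrt(sum((p[1, ] - p[2, ])^2))
    if (dpx < 1e-9) stop("DegenerateGeometry: coincident points")
    ps <- fiducials$template$distance / dpx
    T <- diag(c(ps, ps, 1))
    return(planar_calibration(T, ps, "scale_only"))
  }
  if (k == 3) {
    if (collinear(p)) stop("DegenerateGeometry: collinear points")
    L1 <- fiducials$template$arm1; L2 <- fiducials$template$arm2
    # corner -> (0,0); arm ends onto orthogonal axes: p1 -> (0, L1) (x axis),
    # p2 -> (L2, 0) (y axis). Solve the exact affine from 3 correspondences.
    src <- rbind(p[3, ], p[1, ], p[2, ])
    dst <- rbind(c(0, 0), c(0, L1), c(L2, 0))
    A <- t(solve(cbind(src, 1), dst))     # 2x3: (y,x) mm = A [row col 1]'
    T <- rbind(A, c(0, 0, 1))
    ps <- mean(c(L1 / sqrt(sum((p[1, ] - p[3, ])^2)),
                 L2 / sqrt(sum((p[2, ] - p[3, ])^2))))
    return(planar_calibration(T, ps, "affine"))
  }
  # 4 points: full homography onto the rectangle corners
  if (any_three_collinear(p))
    stop("DegenerateGeometry: three of the four points are collinear")
  w <- fiducials$template$width; h <- fiducials$template$height
  dst <- rbind(c(0, 0), c(0, w), c(h, w), c(h, 0))  # (y, x) mm, TL TR BR BL
  H <- fit_homography(p, dst)
  ps <- mean(c(w / sqrt(sum((p[1, ] - p[2, ])^2)),
               w / sqrt(sum((p[4, ] - p[3, ])^2)),
               h / sqrt(sum((p[1, ] - p[4, ])^2)),
               h / sqrt(sum((p[2, ] - p[3, ])^2))))
  planar_calibration(H, ps, "full_perspective")
}

collinear <- function(p) {
  abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
        (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) < 1e-9 * max(abs(p))^2
}
any_three_collinear <- function(p) {
  any(apply(utils::combn(nrow(p), 3), 2, function(i) collinear(p[i, ])))
}

#' Map photo pixel coordinates to physical mm through a calibration
#' @param calib a [planar_calibration()].
#' @param pts `n x 2` (row, col) pixel coordinates.
#' @return `n x 2` (y, x) mm coordinates.
#' @export
calibrate_points <- function(calib, pts) {
  apply_homography(calib$transform, as.matrix(pts))
}

#' Calibrated photograph
#'
#' @param pixels rectified grayscale image.
#' @param pixel_size isotropic mm/pixel.
#' @param origin_mm mm coordinate of pixel (1, 1) in the physical plane.
#' @return object of class `calibrated_photo`.
#' @export
calibrated_photo <- function(pixels, pixel_size, origin_mm = c(0, 0)) {
  stopifnot(is.matrix(pixels), pixel_size > 0)
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 origin_mm = origin_mm),
            class = "calibrated_photo")
}

#' Rectify a photograph onto a regular mm grid
#'
#' Resamples the photograph through the calibration onto a regular grid
#' of `target_pixel_size`, correcting perspective distortion and fixing
#' the pixel size. Colour inputs are converted to grayscale with
#' luminance weights (0.299, 0.587, 0.114) first; samples outside the
#' source footprint are 0.
#'
#' @param photo a [raw_photo()] or image array.
#' @param calib a [planar_calibration()].
#' @param target_pixel_size output pixel size, mm.
#' @param interp `"linear"` or `"nearest"`.
#' @return a [calibrated_photo()].
#' @export
rectify <- function(photo, calib, target_pixel_size = calib$pixel_size,
                    interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(target_pixel_size > 0)
  img <- as_gray(if (inherits(photo, "raw_photo")) photo$pixels else photo)
  H <- nrow(img); W <- ncol(img)
  corners <- rbind(c(1, 1), c(1, W), c(H, W), c(H, 1))
  mm <- apply_homography(calib$transform, corners)
  ylim <- range(mm[, 1]); xlim <- range(mm[, 2])
  ho <- max(2L, ceiling((ylim[2] - ylim[1]) / target_pixel_size) + 1L)
  wo <- max(2L, ceiling((xlim[2] - xlim[1]) / target_pixel_size) + 1L)
  gy <- ylim[1] + (seq_len(ho) - 1) * target_pixel_size
  gx <- xlim[1] + (seq_len(wo) - 1) * target_pixel_size
  pts <- cbind(rep(gy, times = wo), rep(gx, each = ho))
  Tin <- solve(calib$transform)
  px <- apply_homography(Tin, pts)
  out <- if (interp == "linear") {
    matrix(interp2(img, px[, 2], px[, 1])$v, ho, wo)
  } else {
    rr <- round(px[, 1]); cc <- round(px[, 2])
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    v <- numeric(nrow(px))
    v[ok] <- img[cbind(rr[ok], cc[ok])]
    matrix(v, ho, wo)
  }
  calibrated_photo(out, target_pixel_size, origin_mm = c(ylim[1], xlim[1]))
}

#' Tissue mask of a calibrated photograph
#'
#' Thresholding followed by morphological opening and closing with a disk,
#' removal of small components, and 8-connected component labelling.
#'
#' @param photo a [calibrated_photo()].
#' @param threshold intensity threshold, or `"otsu"` for an automatic
#'   suggestion.
#' @param min_area minimum component area in mm^2.
#' @param morph_radius disk radius for opening/closing, mm.
#' @return object of class `tissue_mask`: `mask` (0/1 matrix),
#'   `components` (integer label matrix), `n_components`, `pixel_size`.
#'   An empty mask is returned with a warning (`EmptyMask`).
#' @export
segment_tissue <- function(photo, threshold = "otsu", min_area = 20,
                           morph_radius = 1) {
  img <- photo$pixels
  p <- photo$pixel_size
  if (identical(threshold, "otsu")) {
    rng <- range(img)
    sc <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
    threshold <- EBImage::otsu(EBImage::Image(sc)) * diff(rng) + rng[1]
  }
  bw <- img > threshold
  r_px <- max(1L, round(morph_radius / p))
  brush <- EBImage::makeBrush(2 * r_px + 1, shape = "disc")
  m <- EBImage::closing(EBImage::opening(bw, brush), brush)
  m <- matrix(as.numeric(m > 0), nrow(img), ncol(img))
  lab <- label_components(m)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas * p^2 >= min_area)
    lab[!(lab %in% keep)] <- 0L
    # relabel contiguously from 1
    if (length(keep)) {
      lab <- array(match(lab, c(0L, sort(keep)), nomatch = 1L) - 1L, dim(lab))
    }
  }
  m <- (lab > 0) * 1
  if (sum(m) == 0) warning("EmptyMask: no tissue component survived")
  structure(list(mask = m, components = lab,
                 n_components = max(lab), pixel_size = p),
            class = "tissue_mask")
}

# 8-connected component labelling (two-pass union-find).
label_components <- function(m) {
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (cc in seq_len(W)) for (rr in seq_len(H)) {
    if (m[rr, cc] == 0) next
    nb <- integer(0)
    if (rr > 1 && lab[rr - 1, cc] > 0) nb <- c(nb, lab[rr - 1, cc])
    if (cc > 1) {
      if (lab[rr, cc - 1] > 0) nb <- c(nb, lab[rr, cc - 1])
      if (rr > 1 && lab[rr - 1, cc - 1] > 0) nb <- c(nb, lab[rr - 1, cc - 1])
      if (rr < H && lab[rr + 1, cc - 1] > 0) nb <- c(nb, lab[rr + 1, cc - 1])
    }
    if (!length(nb)) {
      nxt <- nxt + 1L; parent[nxt] <- nxt; lab[rr, cc] <- nxt
    } else {
      roots <- vapply(unique(nb), find, integer(1))
      r0 <- min(roots)
      lab[rr, cc] <- r0
      for (r in roots) parent[r] <- r0
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, integer(1))
  ids <- match(roots, sort(unique(roots)))
  lab[lab > 0] <- ids[lab[lab > 0]]
  lab
}

#' Group tissue components into anatomical slices
#'
#' Applies a declarative ordering specification: which connected
#' components belong to which anatomical slice (a slice may consist of
#' several components, e.g. a detached temporal pole), and whether the
#' photograph lists slices anterior-first or posterior-first. Records are
#' returned sorted anterior to posterior; component positions are not
#' altered.
#'
#' @param mask a `tissue_mask`.
#' @param ordering list with `order` (`"anterior_first"` or
#'   `"posterior_first"`) and `slices`: a list of integer vectors of
#'   component ids, in the photograph's native order.
#' @return tibble with columns `slice_index` (0-based, anterior to
#'   posterior) and `component_ids` (list column).
#' @export
group_components <- function(mask, ordering) {
  stopifnot(ordering$order %in% c("anterior_first", "posterior_first"))
  ids <- unlist(ordering$slices)
  all_ids <- seq_len(mask$n_components)
  if (anyDuplicated(ids))
    stop("DuplicateAssignment: component assigned to more than one slice")
  missing <- setdiff(all_ids, ids)
  if (length(missing))
    stop("UnassignedComponent: component(s) ",
         paste(missing, collapse = ", "), " not assigned to any slice")
  extra <- setdiff(ids, all_ids)
  if (length(extra))
    stop("UnassignedComponent: unknown component id(s) ",
         paste(extra, collapse = ", "))
  slices <- ordering$slices
  if (ordering$order == "posterior_first") slices <- rev(slices)
  tibble::tibble(slice_index = seq_along(slices) - 1L,
                 component_ids = lapply(slices, as.integer))
}

#' Read a slice-ordering specification from JSON
#'
#' Format: `{"photos": [{"file": ..., "order": "anterior_first",
#' "slices": [[1,2],[3]]}]}`.
#'
#' @param path JSON file path.
#' @return list of per-photo ordering specs.
#' @export
read_ordering <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(js$photos, function(ph)
    list(file = ph$file, order = ph$order,
         slices = lapply(ph$slices, function(s) as.integer(unlist(s)))))
}

#' Build a slice stack from a segmented photograph
#'
#' Extracts each anatomical slice (its components) from a calibrated
#' photograph onto a common in-plane grid, preserving the relative
#' positions of multi-component slices, and stacks them anterior to
#' posterior.
#'
#' @param photo a [calibrated_photo()].
#' @param mask the matching `tissue_mask`.
#' @param records slice records from [group_components()].
#' @param thickness nominal slice thickness, mm.
#' @return a [slice_stack()].
#' @export
photo_to_stack <- function(photo, mask, records, thickness) {
  comp <- mask$components
  n <- nrow(records)
  boxes <- lapply(records$component_ids, function(ids) {
    sel <- matrix(comp %in% ids, nrow(comp), ncol(comp))
    rows <- range(which(rowSums(sel) > 0))
    cols <- range(which(colSums(sel) > 0))
    list(sel = sel, rows = rows, cols = cols)
  })
  hh <- max(vapply(boxes, function(b) diff(b$rows) + 1L, integer(1)))
  ww <- max(vapply(boxes, function(b) diff(b$cols) + 1L, integer(1)))
  imgs <- array(0, c(hh, ww, n)); msks <- array(0, c(hh, ww, n))
  for (i in seq_len(n)) {
    b <- boxes[[i]]
    sub_img <- photo$pixels * b$sel
    r0 <- floor((hh - (diff(b$rows) + 1)) / 2)
    c0 <- floor((ww - (diff(b$cols) + 1)) / 2)
    rr <- seq(b$rows[1], b$rows[2]); cc <- seq(b$cols[1], b$cols[2])
    imgs[r0 + seq_along(rr), c0 + seq_along(cc), i] <- sub_img[rr, cc]
    msks[r0 + seq_along(rr), c0 + seq_along(cc), i] <- b$sel[rr, cc] * 1
  }
  slice_stack(imgs, msks, photo$pixel_size, thickness)
}
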