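# Lightweight scale/rotation-aware keypoint detection and descriptor
# matching for fiducial markers: difference-of-Gaussian keypoints, a
# dominant gradient orientation per keypoint, and orientation-normalized
# intensity patch descriptors compared with a Lowe ratio test. The marker
# templates are user-supplied images, so the detector only needs to be
# repeatable between a template and its (possibly rotated/scaled)
# occurrence in the photograph.

# Detect difference-of-Gaussian keypoints. Returns data.frame with row,
# col, scale (the sigma of the level) and response.
kp_detect <- function(img, n_scales = 3, sigma0 = 1.6, contrast = 0.02,
                      max_kp = 400L) {
  img <- as_gray(img)
  rng <- diff(range(img)); if (rng == 0) return(empty_kp())
  img <- (img - min(img)) / rng
  sig <- sigma0 * 2^(seq(0, n_scales) / 2)
  blur <- lapply(sig, function(s) EBImage::gblur(img, s))
  kps <- list()
  for (k in seq_len(n_scales)) {
    D <- blur[[k + 1]] - blur[[k]]
    H <- nrow(D); W <- ncol(D)
    inner <- D[2:(H - 1), 2:(W - 1)]
    ismax <- abs(inner) > contrast
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      ismax <- ismax & (abs(inner) >= abs(D[2:(H - 1) + dy, 2:(W - 1) + dx]))
    }
    idx <- which(ismax, arr.ind = TRUE)
    if (nrow(idx)) {
      kps[[k]] <- data.frame(row = idx[, 1] + 1, col = idx[, 2] + 1,
                             scale = sig[k], response = abs(inner[idx]))
    }
  }
  kp <- do.call(rbind, kps)
  if (is.null(kp) || !nrow(kp)) return(empty_kp())
  kp <- kp[order(-kp$response), , drop = FALSE]
  kp[seq_len(min(nrow(kp), max_kp)), , drop = FALSE]
}

empty_kp <- function() data.frame(row = numeric(0), col = numeric(0),
                                  scale = numeric(0), response = numeric(0))

# Dominant gradient orientation (radians) of each keypoint, from a 36-bin
# magnitude-weighted histogram over a Gaussian window.
kp_orientations <- function(img, kp) {
  img <- as_gray(img)
  gx <- cbind(img[, 2] - img[, 1],
              (img[, -(1:2), drop = FALSE] - img[, 1:(ncol(img) - 2), drop = FALSE]) / 2,
              img[, ncol(img)] - img[, ncol(img) - 1])
  gy <- rbind(img[2, ] - img[1, ],
              (img[-(1:2), , drop = FALSE] - img[1:(nrow(img) - 2), , drop = FALSE]) / 2,
              img[nrow(img), ] - img[nrow(img) - 1, ])
  mag <- sqrt(gx^2 + gy^2); ang <- atan2(gy, gx)
  H <- nrow(img); W <- ncol(img)
  vapply(seq_len(nrow(kp)), function(i) {
    r <- kp$row[i]; c <- kp$col[i]; s <- kp$scale[i]
    rad <- max(3L, ceiling(2 * s))
    rows <- max(1, r - rad):min(H, r + rad)
    cols <- max(1, c - rad):min(W, c + rad)
    w <- exp(-(outer((rows - r)^2, (cols - c)^2, `+`)) / (2 * (1.5 * s)^2))
    hist36 <- numeric(36)
    b <- pmin(36L, 1L + floor((ang[rows, cols] + pi) / (2 * pi) * 36))
    ww <- w * mag[rows, cols]
    for (j in seq_along(b)) hist36[b[j]] <- hist36[b[j]] + ww[j]
    # parabolic interpolation of the histogram peak for a continuous angle
    pk <- which.max(hist36)
    l <- hist36[(pk - 2) %% 36 + 1]; cme <- hist36[pk]; r <- hist36[pk %% 36 + 1]
    off <- if (cme > l && cme > r) 0.5 * (l - r) / (l - 2 * cme + r) else 0
    (pk - 0.5 + off) / 36 * 2 * pi - pi
  }, numeric(1))
}

# 8x8 orientation-normalized patch descriptor sampled at spacing ~1.5
# scale, z-scored. Rows of the result are unit-norm descriptor vectors.
kp_descriptors <- function(img, kp, ori) {
  img <- as_gray(img)
  n <- nrow(kp)
  out <- matrix(0, n, 64)
  grid <- seq(-3.5, 3.5, length.out = 8)
  for (i in seq_len(n)) {
    sp <- 1.5 * kp$scale[i]
    ca <- cos(ori[i]); sa <- sin(ori[i])
    gx <- outer(rep(1, 8), grid) * sp
    gy <- outer(grid, rep(1, 8)) * sp
    sx <- kp$col[i] + ca * gx - sa * gy
    sy <- kp$row[i] + sa * gx + ca * gy
    v <- interp2(img, sx, sy)$v
    v <- v - mean(v)
    nv <- sqrt(sum(v^2))
    out[i, ] <- if (nv > 0) v / nv else v
  }
  out
}

# Match descriptors from a template (rows of d1) to a photo (rows of d2)
# with the Lowe ratio test. Returns data.frame (i1, i2, dist).
kp_match <- function(d1, d2, lowe_ratio = 0.75, max_dist = 0.4) {
  if (!nrow(d1) || nrow(d2) < 2)
    return(data.frame(i1 = integer(0), i2 = integer(0), dist = numeric(0)))
  # squared distances via cross products (descriptors are unit norm)
  sim <- d1 %*% t(d2)
  dd <- sweep(-2 * sim, 1, rowSums(d1^2), `+`)
  dd <- sweep(dd, 2, rowSums(d2^2), `+`)
  dd[dd < 0] <- 0
  best <- apply(dd, 1, function(r) {
    o <- order(r)[1:2]
    c(o[1], sqrt(r[o[1]]), sqrt(r[o[2]]))
  })
  keep <- best[2, ] < lowe_ratio * best[3, ] & best[2, ] < max_dist
  data.frame(i1 = which(keep), i2 = best[1, keep], dist = best[2, keep])
}

# Similarity fit with iterative outlier trimming: refit keeping matches
# whose residual is below max(2 px, 3 x median residual).
fit_similarity_trimmed <- function(src, dst, rounds = 2L) {
  keep <- seq_len(nrow(src))
  fit <- fit_similarity(src, dst)
  for (i in seq_len(rounds)) {
    res <- sqrt(rowSums((fit$apply(src[keep, , drop = FALSE]) -
                           dst[keep, , drop = FALSE])^2))
    thr <- max(2, 3 * stats::median(res))
    sel <- res <= thr
    if (sum(sel) < 2 || all(sel)) break
    keep <- keep[sel]
    fit <- fit_similarity(src[keep, , drop = FALSE], dst[keep, , drop = FALSE])
  }
  list(fit = fit, inliers = keep)
}

as_gray <- function(img) {
  if (length(dim(img)) == 3) {
    if (dim(img)[3] == 3)
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img <- img[, , 1]
  }
  img
}
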