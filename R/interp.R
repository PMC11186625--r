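# Internal interpolation kernels. All samplers use zero padding outside the
# source footprint and, on request, return the partial derivatives of the
# interpolated value with respect to the (continuous, 1-based) sample
# coordinates, which the registration objective chains through its transform
# parameters.

#' Bilinear sampling of a 2D image
#'
#' Samples `img` at continuous (1-based) pixel coordinates, returning 0
#' outside the image. Optionally returns the spatial derivatives of the
#' interpolant, used by the registration gradient.
#'
#' @param img numeric matrix (rows = y, cols = x).
#' @param x,y numeric vectors/arrays of column and row coordinates.
#' @param grad if `TRUE`, also return `dx` and `dy`.
#' @return list with `v` (values, same shape as `x`) and, if requested,
#'   `dx`, `dy`.
#' @keywords internal
interp2 <- function(img, x, y, grad = FALSE) {
  r <- interp2_multi(list(img), x, y, grad)[[1]]
  r
}

# Sample several images that share one coordinate field. Returns a list of
# per-image results (v and, if grad, dx, dy). The corner bookkeeping is
# done once, which matters because every slice is sampled twice (image +
# mask) at identical positions.
interp2_multi <- function(imgs, x, y, grad = FALSE) {
  H <- nrow(imgs[[1]]); W <- ncol(imgs[[1]])
  dm <- dim_or_len(x)
  x <- as.vector(x); y <- as.vector(y)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0

  ok00 <- y0 >= 1 & y0 <= H & x0 >= 1 & x0 <= W
  ok01 <- y0 >= 1 & y0 <= H & x0 >= 0 & x0 <= W - 1
  ok10 <- y0 >= 0 & y0 <= H - 1 & x0 >= 1 & x0 <= W
  ok11 <- y0 >= 0 & y0 <= H - 1 & x0 >= 0 & x0 <= W - 1
  xc <- pmin.int(pmax.int(x0, 1L), W)
  yc <- pmin.int(pmax.int(y0, 1L), H)
  xc1 <- pmin.int(x0 + 1, W); xc1[xc1 < 1] <- 1L
  yc1 <- pmin.int(y0 + 1, H); yc1[yc1 < 1] <- 1L
  i00 <- (xc - 1) * H + yc
  i01 <- (xc1 - 1) * H + yc
  i10 <- (xc - 1) * H + yc1
  i11 <- (xc1 - 1) * H + yc1

  gx <- 1 - fx; gy <- 1 - fy
  lapply(imgs, function(img) {
    v00 <- img[i00] * ok00
    v01 <- img[i01] * ok01
    v10 <- img[i10] * ok10
    v11 <- img[i11] * ok11
    top <- v00 * gx + v01 * fx
    bot <- v10 * gx + v11 * fx
    out <- list(v = array(top * gy + bot * fy, dim = dm))
    if (grad) {
      out$dx <- array((v01 - v00) * gy + (v11 - v10) * fy, dim = dm)
      out$dy <- array(bot - top, dim = dm)
    }
    out
  })
}

#' Trilinear sampling of a 3D volume
#'
#' @param vol numeric 3D array.
#' @param x,y,z coordinate arrays (1-based, continuous); `x` indexes dim 2,
#'   `y` dim 1, `z` dim 3 (matching `vol[y, x, z]`).
#' @param grad if `TRUE`, return spatial derivatives as well.
#' @param kernel `"linear"` (trilinear) or `"smooth"`: trilinear with the
#'   fractional weights warped by the Hermite smoothstep
#'   `h(f) = f^2 (3 - 2 f)`. The smooth kernel still interpolates the
#'   voxel values exactly but is C1 across voxel boundaries, so objective
#'   gradients stay consistent when a whole grid aligns with the lattice.
#' @keywords internal
interp3 <- function(vol, x, y, z, grad = FALSE, kernel = "linear") {
  d <- dim(vol); H <- d[1]; W <- d[2]; D <- d[3]
  dm <- dim_or_len(x)
  x <- as.vector(x); y <- as.vector(y); z <- as.vector(z)
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0

  okx0 <- x0 >= 1 & x0 <= W; okx1 <- x0 >= 0 & x0 <= W - 1
  oky0 <- y0 >= 1 & y0 <= H; oky1 <- y0 >= 0 & y0 <= H - 1
  okz0 <- z0 >= 1 & z0 <= D; okz1 <- z0 >= 0 & z0 <= D - 1
  xc <- pmin.int(pmax.int(x0, 1L), W)
  yc <- pmin.int(pmax.int(y0, 1L), H)
  zc <- pmin.int(pmax.int(z0, 1L), D)
  xc1 <- pmin.int(pmax.int(x0 + 1, 1L), W)
  yc1 <- pmin.int(pmax.int(y0 + 1, 1L), H)
  zc1 <- pmin.int(pmax.int(z0 + 1, 1L), D)
  HW <- H * W
  b00 <- (xc - 1) * H; b01 <- (xc1 - 1) * H
  p0 <- (zc - 1) * HW; p1 <- (zc1 - 1) * HW

  c000 <- vol[b00 + yc + p0] * (oky0 & okx0 & okz0)
  c010 <- vol[b01 + yc + p0] * (oky0 & okx1 & okz0)
  c100 <- vol[b00 + yc1 + p0] * (oky1 & okx0 & okz0)
  c110 <- vol[b01 + yc1 + p0] * (oky1 & okx1 & okz0)
  c001 <- vol[b00 + yc + p1] * (oky0 & okx0 & okz1)
  c011 <- vol[b01 + yc + p1] * (oky0 & okx1 & okz1)
  c101 <- vol[b00 + yc1 + p1] * (oky1 & okx0 & okz1)
  c111 <- vol[b01 + yc1 + p1] * (oky1 & okx1 & okz1)

  if (kernel == "smooth") {
    dhx <- 6 * fx * (1 - fx); dhy <- 6 * fy * (1 - fy); dhz <- 6 * fz * (1 - fz)
    fx <- fx * fx * (3 - 2 * fx)
    fy <- fy * fy * (3 - 2 * fy)
    fz <- fz * fz * (3 - 2 * fz)
  } else {
    dhx <- dhy <- dhz <- 1
  }
  a00 <- c000 * (1 - fx) + c010 * fx
  a10 <- c100 * (1 - fx) + c110 * fx
  a01 <- c001 * (1 - fx) + c011 * fx
  a11 <- c101 * (1 - fx) + c111 * fx
  b0 <- a00 * (1 - fy) + a10 * fy
  b1 <- a01 * (1 - fy) + a11 * fy
  out <- list(v = array(b0 * (1 - fz) + b1 * fz, dim = dm))
  if (grad) {
    dx0 <- (c010 - c000) * (1 - fy) + (c110 - c100) * fy
    dx1 <- (c011 - c001) * (1 - fy) + (c111 - c101) * fy
    out$dx <- array((dx0 * (1 - fz) + dx1 * fz) * dhx, dim = dm)
    out$dy <- array(((a10 - a00) * (1 - fz) + (a11 - a01) * fz) * dhy, dim = dm)
    out$dz <- array((b1 - b0) * dhz, dim = dm)
  }
  out
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Nearest-neighbour sampling of a 3D volume (for label maps)
#' @keywords internal
interp3_nn <- function(vol, x, y, z) {
  d <- dim(vol); H <- d[1]; W <- d[2]; D <- d[3]
  dm <- dim_or_len(x)
  iy <- round(as.vector(y)); ix <- round(as.vector(x)); iz <- round(as.vector(z))
  ok <- iy >= 1 & iy <= H & ix >= 1 & ix <= W & iz >= 1 & iz <= D
  iyc <- pmin.int(pmax.int(iy, 1L), H)
  ixc <- pmin.int(pmax.int(ix, 1L), W)
  izc <- pmin.int(pmax.int(iz, 1L), D)
  v <- vol[(izc - 1) * H * W + (ixc - 1) * H + iyc]
  v[!ok] <- 0
  array(v, dim = dm)
}

# 2x (or kx) block-mean downsampling of a matrix or 3D array; trailing rows /
# columns that do not fill a block are dropped. Used by the multi-resolution
# pyramid.
block_mean <- function(a, k = 2L) {
  if (is.matrix(a)) {
    H <- (nrow(a) %/% k) * k; W <- (ncol(a) %/% k) * k
    a <- a[seq_len(H), seq_len(W), drop = FALSE]
    m <- array(a, dim = c(k, H / k, k, W / k))
    out <- apply(m, c(2, 4), mean)
    return(out)
  }
  d <- dim(a)
  dd <- (d %/% k) * k
  a <- a[seq_len(dd[1]), seq_len(dd[2]), seq_len(dd[3]), drop = FALSE]
  m <- array(a, dim = c(k, dd[1] / k, k, dd[2] / k, k, dd[3] / k))
  apply(m, c(2, 4, 6), mean)
}

# Separable Gaussian blur of a 3D array (reflecting borders). Used to
# soften a binary reference during optimization so the trilinear
# interpolant (and hence the objective) is smooth at voxel boundaries.
blur3 <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  r <- max(1L, ceiling(2.5 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); k <- k / sum(k)
  conv_along <- function(a, dim_i) {
    d <- dim(a)
    perm <- switch(dim_i, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, dp[1], dp[2] * dp[3])
    n <- dp[1]
    idx <- function(i) pmin(pmax(i, 1L), n)  # replicate border
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[idx(seq_len(n) + j - r - 1L), , drop = FALSE]
    array(out, dp) -> ap2
    aperm(ap2, order(perm))
  }
  vol <- conv_along(vol, 1L)
  vol <- conv_along(vol, 2L)
  conv_along(vol, 3L)
}

# Smooth random field: low-resolution iid Gaussian noise upsampled to `dims`
# by linear interpolation. `smoothness` is the control-point spacing in
# voxels (larger = smoother). Returns array of dim `dims` with sd ~ `sd`.
smooth_noise_field <- function(dims, smoothness, sd = 1) {
  dims <- as.integer(dims)
  nctrl <- pmax(2L, as.integer(ceiling(dims / smoothness)) + 1L)
  if (length(dims) == 2) {
    ctrl <- matrix(stats::rnorm(prod(nctrl), sd = sd), nctrl[1], nctrl[2])
    gy <- seq(1, nctrl[1], length.out = dims[1])
    gx <- seq(1, nctrl[2], length.out = dims[2])
    xx <- matrix(rep(gx, each = dims[1]), dims[1], dims[2])
    yy <- matrix(rep(gy, times = dims[2]), dims[1], dims[2])
    interp2(ctrl, xx, yy)$v
  } else {
    ctrl <- array(stats::rnorm(prod(nctrl), sd = sd), dim = nctrl)
    gy <- seq(1, nctrl[1], length.out = dims[1])
    gx <- seq(1, nctrl[2], length.out = dims[2])
    gz <- seq(1, nctrl[3], length.out = dims[3])
    yy <- array(rep(gy, times = dims[2] * dims[3]), dim = dims)
    xx <- array(rep(rep(gx, each = dims[1]), times = dims[3]), dim = dims)
    zz <- array(rep(gz, each = dims[1] * dims[2]), dim = dims)
    interp3(ctrl, xx, yy, zz)$v
  }
}
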