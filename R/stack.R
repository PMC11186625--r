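#' Ordered stack of photographed slices
#'
#' The object being reconstructed: an ordered (anterior to posterior)
#' sequence of grayscale slice images with tissue masks on a common
#' in-plane grid, plus the pixel size and the nominal cutting thickness.
#'
#' @param images numeric 3D array `H x W x N` (or list of `N` matrices) of
#'   grayscale slice intensities.
#' @param masks array/list of the same shape with values in `[0, 1]`
#'   (binary or soft tissue masks).
#' @param pixel_size in-plane pixel size in mm (isotropic).
#' @param thickness nominal slice thickness in mm.
#' @return an object of class `slice_stack` with elements `images`, `masks`
#'   (both `H x W x N` arrays), `pixel_size`, `thickness`, `n`.
#' @export
slice_stack <- function(images, masks, pixel_size, thickness) {
  as_arr <- function(x) {
    if (is.list(x)) x <- array(unlist(x), dim = c(dim(x[[1]]), length(x)))
    if (length(dim(x)) == 2) x <- array(x, dim = c(dim(x), 1))
    x
  }
  images <- as_arr(images); masks <- as_arr(masks)
  stopifnot(identical(dim(images), dim(masks)),
            pixel_size > 0, thickness > 0)
  if (dim(images)[3] < 2) stop("a slice_stack needs at least 2 slices")
  if (min(masks) < 0 || max(masks) > 1)
    stop("masks must lie in [0, 1]")
  structure(list(images = images, masks = masks,
                 pixel_size = pixel_size, thickness = thickness,
                 n = dim(images)[3]),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<slice_stack> %d slices of %d x %d px (%.3g mm/px), nominal thickness %.3g mm\n",
              x$n, d[1], d[2], x$pixel_size, x$thickness))
  invisible(x)
}

# In-plane physical coordinates (mm) of an H x W grid, origin at the grid
# centre. Returns matrices X (along columns) and Y (along rows).
grid_mm <- function(H, W, pixel_size) {
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  list(X = matrix(rep((seq_len(W) - cx) * pixel_size, each = H), H, W),
       Y = matrix(rep((seq_len(H) - cy) * pixel_size, times = W), H, W),
       cx = cx, cy = cy)
}

# Anterior-posterior (slab) mm coordinates of the N slabs for scale s:
# slab n (1-based) sits at (n - (N+1)/2) * s * thickness, centred on 0.
slab_z <- function(n_slices, s, thickness) {
  (seq_len(n_slices) - (n_slices + 1) / 2) * s * thickness
}

# Resample one slice through the planar transform theta onto an output grid
# of shape out_hw (defaults to the slice's own shape), both grids sharing
# pixel_size and centred origins. Output pixel at mm coordinate u shows the
# slice at v = A^{-1} (u - b) (pull resampling of the forward map
# u = A v + b). If grad = TRUE, returns the derivative of every output
# pixel with respect to each parameter of theta.
resample_slice <- function(img, theta, pixel_size, out_hw = dim(img),
                           grad = FALSE) {
  resample_slice_multi(list(img), theta, pixel_size, dim(img), out_hw,
                       grad)[[1]]
}

# Resample several channels (e.g. a slice image and its mask) that share
# one planar transform and one source grid shape `src_hw`.
resample_slice_multi <- function(channels, theta, pixel_size, src_hw,
                                 out_hw = src_hw, grad = FALSE) {
  p <- phi_matrix(theta)
  Ainv <- solve(p$A)
  g <- grid_mm(out_hw[1], out_hw[2], pixel_size)
  ux <- g$X - p$b[1]; uy <- g$Y - p$b[2]
  vx <- Ainv[1, 1] * ux + Ainv[1, 2] * uy
  vy <- Ainv[2, 1] * ux + Ainv[2, 2] * uy
  src <- grid_mm(src_hw[1], src_hw[2], pixel_size)
  px <- vx / pixel_size + src$cx
  py <- vy / pixel_size + src$cy
  its <- interp2_multi(channels, px, py, grad = grad)
  if (!grad) return(lapply(its, function(it) list(v = it$v)))
  pg <- phi_matrix_grad(theta)
  npar <- length(theta)
  # dv/dtheta_k = -Ainv (dA_k v + db_k), shared across channels
  dvx <- vector("list", npar); dvy <- vector("list", npar)
  for (k in seq_len(npar)) {
    dAk <- pg$dA[[k]]; dbk <- pg$db[[k]]
    wx <- dAk[1, 1] * vx + dAk[1, 2] * vy + dbk[1]
    wy <- dAk[2, 1] * vx + dAk[2, 2] * vy + dbk[2]
    dvx[[k]] <- -(Ainv[1, 1] * wx + Ainv[1, 2] * wy)
    dvy[[k]] <- -(Ainv[2, 1] * wx + Ainv[2, 2] * wy)
  }
  lapply(its, function(it) {
    gx <- it$dx / pixel_size; gy <- it$dy / pixel_size
    dv <- vector("list", npar)
    for (k in seq_len(npar)) dv[[k]] <- gx * dvx[[k]] + gy * dvy[[k]]
    list(v = it$v, dtheta = dv)
  })
}

#' Assemble a slice stack into a reconstructed volume
#'
#' Resamples every slice (image and mask) through its planar transform and
#' stacks the results into `H x W x N` volumes whose anterior-posterior
#' slab spacing is `s * thickness`. This is the reconstructed-volume
#' operator of the registration objective: slab `n` holds slice `n`
#' resampled through its transform, and the voxel-to-mm mapping places
#' slabs at `(n - (N+1)/2) * s * thickness` along the slicing axis.
#'
#' @param stack a [slice_stack()].
#' @param params a `recon_params` object (see [init_params()]) or a list
#'   with `phi` (list of planar parameter vectors), `s` (anterior-posterior
#'   scale) and optionally `psi`.
#' @param out_hw output in-plane grid shape (defaults to the stack's).
#' @return list of class `recon_volume`: `image` and `mask` (`H x W x N`
#'   arrays), `pixel_size`, `slab_spacing` (`s * thickness` in mm), `z`
#'   (slab centre coordinates, mm), and `affine` (4x4 voxel-to-mm matrix).
#' @export
assemble <- function(stack, params, out_hw = dim(stack$images)[1:2]) {
  N <- stack$n
  stopifnot(length(params$phi) == N)
  img <- array(0, c(out_hw, N)); msk <- array(0, c(out_hw, N))
  src_hw <- dim(stack$images)[1:2]
  for (n in seq_len(N)) {
    rs <- resample_slice_multi(list(stack$images[, , n], stack$masks[, , n]),
                               params$phi[[n]], stack$pixel_size, src_hw,
                               out_hw)
    img[, , n] <- rs[[1]]$v
    msk[, , n] <- rs[[2]]$v
  }
  msk[msk < 0] <- 0; msk[msk > 1] <- 1
  sp <- params$s * stack$thickness
  z <- slab_z(N, params$s, stack$thickness)
  aff <- diag(4)
  aff[1, 1] <- stack$pixel_size; aff[2, 2] <- stack$pixel_size; aff[3, 3] <- sp
  aff[1:3, 4] <- c(-(out_hw[2] + 1) / 2 * stack$pixel_size,
                   -(out_hw[1] + 1) / 2 * stack$pixel_size,
                   z[1] - sp)
  structure(list(image = img, mask = msk, pixel_size = stack$pixel_size,
                 slab_spacing = sp, z = z, affine = aff),
            class = "recon_volume")
}
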