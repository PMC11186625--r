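# Digital slicing of a 3D volume into a distorted photo stack with known
# ground-truth poses, and the mean-voxel-displacement error between a
# reconstruction and that ground truth.

#' Digital slicing configuration
#'
#' Controls how a volume is cut into simulated dissection photographs:
#' every `spacing`-th plane along the slicing axis is extracted (thickness
#' `spacing * voxel`), the cut position of slice `n` is jittered uniformly
#' over `[n - jitter, n + jitter]` (in slice units), and each extracted
#' slice receives an independent random planar affine distortion and a
#' multiplicative smooth illumination field.
#'
#' @param spacing integer `S >= 1`: slices are `S * voxel` mm thick.
#' @param jitter thickness jitter `j >= 0` in slice units.
#' @param max_translation,max_rotation per-slice distortion bounds
#'   (mm / degrees).
#' @param max_log_scale,max_shear affine distortion bounds; set all four
#'   bounds to 0 for undistorted slices.
#' @param illumination_amplitude max `|log field|` of the per-slice
#'   multiplicative illumination field (0 disables it).
#' @param illumination_smoothness control-point spacing of the field, px.
#' @param min_foreground slices whose extracted mask has fewer foreground
#'   pixels than this are discarded (a photographed stack only contains
#'   slices showing tissue). Set to 0 to keep every cut.
#' @param seed integer seed; the whole simulation is reproducible.
#' @return object of class `slicing_config`.
#' @export
slicing_config <- function(spacing = 4L, jitter = 0,
                           max_translation = 5, max_rotation = 10,
                           max_log_scale = 0.1, max_shear = 0.1,
                           illumination_amplitude = 0.2,
                           illumination_smoothness = 16,
                           min_foreground = 16L,
                           seed = 1L) {
  stopifnot(spacing >= 1, jitter >= 0, illumination_amplitude >= 0)
  structure(list(spacing = as.integer(spacing), jitter = jitter,
                 max_translation = max_translation,
                 max_rotation = max_rotation,
                 max_log_scale = max_log_scale, max_shear = max_shear,
                 illumination_amplitude = illumination_amplitude,
                 illumination_smoothness = illumination_smoothness,
                 min_foreground = as.integer(min_foreground),
                 seed = as.integer(seed)),
            class = "slicing_config")
}

#' Digitally slice a volume into a simulated photo stack
#'
#' Extracts coronal planes from an intensity volume at every
#' `spacing`-th voxel (with optional thickness jitter), distorts each
#' slice with a random planar affine and illumination field, and records
#' the ground-truth pose of every slice. The result feeds
#' [reconstruct()] and [reconstruction_error()].
#'
#' @param volume 3D intensity array (slicing axis = 3rd dimension).
#' @param mask 3D binary mask of the same shape.
#' @param cfg a [slicing_config()].
#' @param voxel_size isotropic voxel size of `volume` in mm.
#' @return object of class `simulated_stack`: `stack` (a [slice_stack()]
#'   with `pixel_size = voxel_size` and `thickness = spacing * voxel_size`),
#'   `truth` (per-slice forward maps photo -> volume mm and true
#'   anterior-posterior positions), `source` (volume, mask, voxel_size),
#'   `config`.
#' @export
digitally_slice <- function(volume, mask, cfg = slicing_config(),
                            voxel_size = 1) {
  d <- dim(volume)
  stopifnot(identical(dim(mask), d), d[3] >= 2 * cfg$spacing)
  S <- cfg$spacing
  N <- d[3] %/% S
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  H <- d[1]; W <- d[2]
  images <- array(0, c(H, W, N)); masks <- array(0, c(H, W, N))
  truth_phi <- vector("list", N)
  z_true <- numeric(N)
  zc <- (d[3] + 1) / 2

  extract_plane <- function(vol, pos) {
    p0 <- floor(pos); f <- pos - p0
    p0 <- min(max(p0, 1L), d[3])
    p1 <- min(p0 + 1L, d[3])
    vol[, , p0] * (1 - f) + vol[, , p1] * f
  }

  for (n in seq_len(N)) {
    base <- 1 + (n - 1) * S
    off <- if (cfg$jitter > 0) stats::runif(1, -cfg$jitter * S, cfg$jitter * S) else 0
    pos <- min(max(base + off, 1), d[3])
    img <- extract_plane(volume, pos)
    msk <- extract_plane(mask, pos)

    # random distortion: photo(u) = plane(A u + b) (pull map), so the
    # ground-truth forward map photo -> volume plane is u |-> A u + b
    th <- c(stats::runif(2, -cfg$max_translation, cfg$max_translation),
            stats::runif(1, -cfg$max_rotation, cfg$max_rotation) * pi / 180,
            stats::runif(2, -cfg$max_log_scale, cfg$max_log_scale),
            stats::runif(1, -cfg$max_shear, cfg$max_shear))
    if (cfg$max_translation == 0 && cfg$max_rotation == 0 &&
        cfg$max_log_scale == 0 && cfg$max_shear == 0) th <- numeric(6)
    pm <- phi_matrix(th)
    # resample_slice pulls through the inverse of its forward map, so to
    # realize photo(u) = plane(A u + b) we hand it the inverse transform.
    Ainv <- solve(pm$A); binv <- -as.vector(Ainv %*% pm$b)
    img_d <- resample_generic(img, Ainv, binv, voxel_size)
    msk_d <- resample_generic(msk, Ainv, binv, voxel_size)

    if (cfg$illumination_amplitude > 0) {
      f <- smooth_noise_field(c(H, W), cfg$illumination_smoothness)
      f <- f / max(abs(f)) * cfg$illumination_amplitude
      img_d <- img_d * exp(f)
    }
    images[, , n] <- img_d
    masks[, , n] <- (msk_d >= 0.5) * 1
    truth_phi[[n]] <- list(A = pm$A, b = pm$b)
    z_true[n] <- (pos - zc) * voxel_size
  }

  keep <- which(apply(masks, 3, sum) >= cfg$min_foreground)
  if (length(keep) < 2)
    stop("fewer than 2 slices with tissue; lower min_foreground or spacing")
  images <- images[, , keep, drop = FALSE]
  masks <- masks[, , keep, drop = FALSE]
  truth_phi <- truth_phi[keep]
  z_true <- z_true[keep]
  stack <- slice_stack(images, masks, pixel_size = voxel_size,
                       thickness = S * voxel_size)
  structure(list(stack = stack,
                 truth = list(phi = truth_phi, z = z_true),
                 source = list(volume = volume, mask = mask,
                               voxel_size = voxel_size),
                 config = cfg),
            class = "simulated_stack")
}

# Resample a 2D image through forward planar map u -> A u + b (both grids
# share pixel size and centred mm origins).
resample_generic <- function(img, A, b, pixel_size) {
  # direct pull: out(u) = img(A^{-1}(u - b))
  Ainv <- solve(A)
  g <- grid_mm(nrow(img), ncol(img), pixel_size)
  ux <- g$X - b[1]; uy <- g$Y - b[2]
  vx <- Ainv[1, 1] * ux + Ainv[1, 2] * uy
  vy <- Ainv[2, 1] * ux + Ainv[2, 2] * uy
  interp2(img, vx / pixel_size + g$cx, vy / pixel_size + g$cy)$v
}

#' @export
print.simulated_stack <- function(x, ...) {
  cat(sprintf("<simulated_stack> %d slices (spacing %d, jitter %.2g, seed %d)\n",
              x$stack$n, x$config$spacing, x$config$jitter, x$config$seed))
  invisible(x)
}

#' Mean voxel displacement between a reconstruction and ground truth
#'
#' For every foreground voxel of every slice, composes the recovered pose
#' (slice transform, slab position and reference transform) with the
#' inverse ground-truth pose and measures the displacement in mm. The mean
#' over all foreground voxels is reported after an optimal global rigid
#' alignment of the two point sets, which removes the irrelevant common
#' pose of the whole stack.
#'
#' @param result a `recon_result` from [reconstruct()].
#' @param sim the `simulated_stack` holding the ground truth.
#' @param align if `TRUE` (default) remove the best global rigid motion
#'   before averaging.
#' @return mean displacement in mm.
#' @export
reconstruction_error <- function(result, sim, align = TRUE) {
  stack <- sim$stack
  N <- stack$n
  if (length(result$params$phi) != N)
    stop("CountMismatch: result and ground truth have different slice counts")
  p <- stack$pixel_size
  g <- grid_mm(dim(stack$masks)[1], dim(stack$masks)[2], p)
  pm <- psi_matrix(result$params$psi)
  z_rec <- slab_z(N, result$params$s, stack$thickness)

  rec <- list(); tru <- list()
  for (n in seq_len(N)) {
    m <- stack$masks[, , n] > 0.5
    if (!any(m)) next
    ux <- g$X[m]; uy <- g$Y[m]
    ph <- phi_matrix(result$params$phi[[n]])
    sx <- ph$A[1, 1] * ux + ph$A[1, 2] * uy + ph$b[1]
    sy <- ph$A[2, 1] * ux + ph$A[2, 2] * uy + ph$b[2]
    q <- cbind(sx, sy, z_rec[n]) %*% t(pm$L)
    q <- sweep(q, 2, pm$t, `+`)
    tA <- sim$truth$phi[[n]]$A; tb <- sim$truth$phi[[n]]$b
    tx <- tA[1, 1] * ux + tA[1, 2] * uy + tb[1]
    ty <- tA[2, 1] * ux + tA[2, 2] * uy + tb[2]
    rec[[length(rec) + 1]] <- q
    tru[[length(tru) + 1]] <- cbind(tx, ty, sim$truth$z[n])
  }
  P <- do.call(rbind, rec); Q <- do.call(rbind, tru)
  if (align) P <- kabsch_align(P, Q)
  mean(sqrt(rowSums((P - Q)^2)))
}

# Optimal rigid alignment (rotation + translation) of P onto Q, returning
# the transformed P (Kabsch, closed form).
kabsch_align <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  Cv <- t(P0) %*% Q0
  sv <- svd(Cv)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(P0 %*% t(R), 2, cq, `+`)
}
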