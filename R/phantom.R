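# Synthetic hemisphere phantoms: nested ellipsoids/boxes with integer
# labels emulating white matter, a cortical shell, a ventricle and deep
# gray blobs. They stand in for real isotropic MRI volumes so the digital
# slicing experiments and the generative model can run without any data
# download.

#' Phantom specification
#'
#' Describes a multi-label 3D phantom: grid, voxel size and a list of
#' geometric structures painted in order (later structures overwrite
#' earlier ones, which is how nesting is expressed).
#'
#' @param dims grid shape `(rows, cols, slabs)`.
#' @param voxel_size isotropic voxel size in mm.
#' @param structures list of structures, each a list with `label`
#'   (positive integer), `type` (`"ellipsoid"` or `"box"`), `center`
#'   (voxel coordinates, `(y, x, z)`), `semiaxes` (voxels), `value`
#'   (base intensity).
#' @param cut optional planar cut emulating the flat medial face of a
#'   hemisphere: a list with `axis` (1 = rows, 2 = cols), `frac` (the cut
#'   plane sits at `center - frac * extent/2` along that axis; everything
#'   below is removed). `NULL` disables the cut.
#' @param seed integer seed controlling the smooth intensity noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(48, 48, 64), voxel_size = 1,
                         structures = NULL,
                         cut = list(axis = 2, frac = 0.55), seed = 1L) {
  if (is.null(structures)) structures <- default_structures(dims)
  labs <- vapply(structures, `[[`, numeric(1), "label")
  stopifnot(all(labs > 0), !anyDuplicated(labs), voxel_size > 0)
  for (st in structures) {
    if (any(st$center - st$semiaxes < 1) || any(st$center + st$semiaxes > dims))
      stop(sprintf("OverlapError: structure label %d exceeds the grid",
                   st$label))
  }
  structure(list(dims = as.integer(dims), voxel_size = voxel_size,
                 structures = structures, cut = cut, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Hemisphere-like default: cortical shell (2) containing white matter (1),
# a ventricle (3) and four deep-gray blobs (4-7).
default_structures <- function(dims) {
  c0 <- (dims + 1) / 2
  # wider than tall in-plane, as coronal slices are; the anisotropy also
  # makes per-slice rotation well determined by the masks. The slight AP
  # shrink leaves room for the lobe modulation of the shell.
  sa <- (dims / 2 - 2) * c(0.72, 1, 0.93)
  list(
    list(label = 2, type = "ellipsoid", center = c0,
         semiaxes = sa, value = 70, lobes = 5, lobe_amp = 0.1), # cortex shell
    list(label = 1, type = "ellipsoid", center = c0,
         semiaxes = sa * 0.78, value = 110, lobes = 5,
         lobe_amp = 0.08),                                 # white matter
    list(label = 3, type = "ellipsoid", center = c0 + c(2, 0, -2),
         semiaxes = sa * c(0.18, 0.14, 0.35), value = 30), # ventricle
    list(label = 4, type = "ellipsoid", center = c0 + c(-6, 5, 4),
         semiaxes = sa * 0.12, value = 85),
    list(label = 5, type = "ellipsoid", center = c0 + c(-6, -5, 4),
         semiaxes = sa * 0.12, value = 90),
    list(label = 6, type = "ellipsoid", center = c0 + c(6, 5, 7),
         semiaxes = sa * 0.10, value = 95),
    list(label = 7, type = "box", center = c0 + c(6, -5, 7),
         semiaxes = sa * 0.10, value = 100))
}

#' Generate a multi-label phantom volume
#'
#' Paints the structures of a [phantom_spec()] into a label volume and
#' renders a matching intensity volume as per-label base values plus a
#' smooth random field. Deterministic for a fixed spec (including its
#' seed).
#'
#' @param spec a [phantom_spec()].
#' @param noise_sd standard deviation of the smooth intensity noise.
#' @param noise_smoothness control-point spacing of the noise, voxels.
#' @return list with `labels` (integer array), `intensity` (numeric
#'   array), `mask` (labels > 0), `voxel_size`.
#' @export
make_phantom <- function(spec = phantom_spec(), noise_sd = 4,
                         noise_smoothness = 6) {
  d <- spec$dims
  iy <- slice.index(array(0L, d), 1)
  ix <- slice.index(array(0L, d), 2)
  iz <- slice.index(array(0L, d), 3)
  labels <- array(0L, d)
  values <- numeric(max(vapply(spec$structures, `[[`, numeric(1), "label")))
  for (st in spec$structures) {
    u <- (iy - st$center[1]) / st$semiaxes[1]
    v <- (ix - st$center[2]) / st$semiaxes[2]
    w <- (iz - st$center[3]) / st$semiaxes[3]
    inside <- if (st$type == "ellipsoid") {
      r2 <- u^2 + v^2 + w^2
      if (is.null(st$lobes) || st$lobes == 0) r2 <= 1
      else {
        # lobed surface emulating cortical folds: the radius is modulated
        # by smooth angular harmonics, so cross-sectional shape varies
        # along every axis and slices carry orientation information
        amp <- if (is.null(st$lobe_amp)) 0.1 else st$lobe_amp
        mod <- 1 + amp * sin(st$lobes * atan2(v, u)) * cos(2.5 * w * pi / 2) +
          0.6 * amp * cos((st$lobes - 1) * atan2(w, u + 1e-9))
        r2 <= mod^2
      }
    } else abs(u) <= 1 & abs(v) <= 1 & abs(w) <= 1
    labels[inside] <- as.integer(st$label)
    values[st$label] <- st$value
  }
  if (!is.null(spec$cut)) {
    ax <- list(iy, ix, iz)[[spec$cut$axis]]
    lim <- (d[spec$cut$axis] + 1) / 2 - spec$cut$frac * d[spec$cut$axis] / 2
    labels[ax < lim] <- 0L
  }
  intensity <- array(0, d)
  fg <- labels > 0
  intensity[fg] <- values[labels[fg]]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  intensity <- intensity + smooth_noise_field(d, noise_smoothness, noise_sd)
  intensity[!fg] <- 0
  list(labels = labels, intensity = intensity, mask = (labels > 0) * 1,
       voxel_size = spec$voxel_size)
}

# Save/restore the global RNG state so seeded generators do not disturb
# the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
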