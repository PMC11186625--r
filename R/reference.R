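#' Reference volume guiding the reconstruction
#'
#' Wraps a 3D array used as the external shape reference: either a binary
#' mask obtained by rasterizing a surface scan (`kind = "surface_mask"`) or
#' a probabilistic atlas with voxelwise probabilities in `[0, 1]`
#' (`kind = "probabilistic_atlas"`). Physical coordinates are mm, with the
#' origin at the centre of the array and axes `(x, y, z)` mapping to array
#' dimensions `(2, 1, 3)`.
#'
#' @param volume numeric 3D array with values in `[0, 1]`.
#' @param voxel_size voxel size in mm; a scalar (isotropic) or a length-3
#'   vector `(x, y, z)`.
#' @param kind `"surface_mask"` (values must be 0/1) or
#'   `"probabilistic_atlas"`.
#' @param origin optional mm coordinate of the array centre in the source
#'   frame (kept as metadata).
#' @return an object of class `reference_volume`.
#' @export
reference_volume <- function(volume, voxel_size,
                             kind = c("surface_mask", "probabilistic_atlas"),
                             origin = c(0, 0, 0)) {
  kind <- match.arg(kind)
  stopifnot(length(dim(volume)) == 3, all(voxel_size > 0))
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  rng <- range(volume)
  if (rng[1] < 0 || rng[2] > 1)
    stop("reference values must lie in [0, 1]")
  if (kind == "surface_mask" && any(volume != 0 & volume != 1))
    stop("a surface_mask reference must be binary")
  if (sum(volume) == 0) stop("EmptyReference: reference has no foreground")
  structure(list(volume = volume, voxel_size = voxel_size, kind = kind,
                 origin = origin),
            class = "reference_volume")
}

#' @export
print.reference_volume <- function(x, ...) {
  cat(sprintf("<reference_volume> %s, %s voxels at %s mm\n", x$kind,
              paste(dim(x$volume), collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x")))
  invisible(x)
}

# mm coordinate of reference array centre (1-based voxel index of centre).
ref_centre_idx <- function(ref) (dim(ref$volume) + 1) / 2

# Convert reference mm coordinates (arrays qx, qy, qz) to continuous voxel
# indices for interp3.
ref_mm_to_idx <- function(ref, qx, qy, qz) {
  ci <- ref_centre_idx(ref)
  list(x = qx / ref$voxel_size[1] + ci[2],
       y = qy / ref$voxel_size[2] + ci[1],
       z = qz / ref$voxel_size[3] + ci[3])
}

# Foreground-weighted centroid of the reference, in its mm frame.
ref_centroid_mm <- function(ref) {
  d <- dim(ref$volume)
  w <- ref$volume
  tot <- sum(w)
  ci <- ref_centre_idx(ref)
  iy <- slice.index(w, 1); ix <- slice.index(w, 2); iz <- slice.index(w, 3)
  c(sum(w * (ix - ci[2])) / tot * ref$voxel_size[1],
    sum(w * (iy - ci[1])) / tot * ref$voxel_size[2],
    sum(w * (iz - ci[3])) / tot * ref$voxel_size[3])
}
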