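# File interchange: NIfTI volumes (via RNifti), PNG slice/mask stacks with
# a JSON ground-truth sidecar, and JSON parameter dumps.

#' Read a NIfTI volume
#'
#' @param path `.nii` / `.nii.gz` file.
#' @return list with `volume` (array) and `voxel_size` (length 3, mm).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vx <- RNifti::pixdim(img)
  list(volume = as.array(img), voxel_size = vx[seq_len(3)])
}

#' Write a volume as NIfTI
#'
#' @param volume 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size scalar or length-3 voxel size in mm.
#' @export
write_volume <- function(volume, path, voxel_size = 1) {
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  img <- RNifti::asNifti(volume, pixdim = c(voxel_size))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a reconstructed volume as NIfTI
#'
#' Writes the intensity and mask volumes of a [reconstruct()] result with
#' the anisotropic voxel dimensions of the stack grid
#' (`pixel_size x pixel_size x s * thickness`).
#'
#' @param result a `recon_result`.
#' @param path output path for the intensity volume; the mask is written
#'   alongside with suffix `_mask`.
#' @export
write_reconstruction <- function(result, path) {
  v <- result$volume
  vx <- c(v$pixel_size, v$pixel_size, v$slab_spacing)
  write_volume(v$image, path, vx)
  mp <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
  write_volume(v$mask, mp, vx)
  invisible(path)
}

#' Save reconstruction parameters as JSON
#'
#' @param params a `recon_params`.
#' @param path output JSON path.
#' @export
write_params <- function(params, path) {
  jsonlite::write_json(list(mode = params$mode,
                            s = params$s,
                            psi = params$psi,
                            phi = params$phi),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load reconstruction parameters from JSON
#' @param path JSON path written by [write_params()].
#' @return a `recon_params`.
#' @export
read_params <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(phi = lapply(seq_len(nrow(js$phi)), function(i) js$phi[i, ]),
                 s = js$s, psi = js$psi, mode = js$mode),
            class = "recon_params")
}

#' Write a simulated stack to a directory
#'
#' PNG slice and mask images plus a `truth.json` sidecar carrying the
#' ground-truth poses, anterior-posterior positions, seed and the full
#' slicing configuration.
#'
#' @param sim a `simulated_stack`.
#' @param dir output directory (created if missing).
#' @export
write_simulated_stack <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  N <- sim$stack$n
  rng <- range(sim$stack$images)
  for (n in seq_len(N)) {
    img <- sim$stack$images[, , n]
    img <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
    png::writePNG(img, file.path(dir, sprintf("slice_%03d.png", n)))
    png::writePNG(sim$stack$masks[, , n],
                  file.path(dir, sprintf("mask_%03d.png", n)))
  }
  truth <- list(
    pixel_size = sim$stack$pixel_size,
    thickness = sim$stack$thickness,
    intensity_range = rng,
    z = sim$truth$z,
    phi = lapply(sim$truth$phi, function(p)
      list(A = as.vector(p$A), b = p$b)),
    config = unclass(sim$config))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a slice stack from a directory of PNGs
#'
#' Expects `slice_***.png` / `mask_***.png` pairs and, optionally, the
#' `truth.json` written by [write_simulated_stack()].
#'
#' @param dir directory path.
#' @param pixel_size,thickness used when no `truth.json` is present.
#' @return a [slice_stack()]; if ground truth is available it is attached
#'   as attribute `"truth"`.
#' @export
read_stack <- function(dir, pixel_size = 1, thickness = 4) {
  sl <- sort(list.files(dir, pattern = "^slice_.*\\.png$", full.names = TRUE))
  mk <- sort(list.files(dir, pattern = "^mask_.*\\.png$", full.names = TRUE))
  stopifnot(length(sl) >= 2, length(sl) == length(mk))
  imgs <- lapply(sl, function(p) as_gray(png::readPNG(p)))
  msks <- lapply(mk, function(p) (as_gray(png::readPNG(p)) >= 0.5) * 1)
  tj <- file.path(dir, "truth.json")
  truth <- NULL
  if (file.exists(tj)) {
    js <- jsonlite::read_json(tj, simplifyVector = TRUE)
    pixel_size <- js$pixel_size; thickness <- js$thickness
    rng <- js$intensity_range
    imgs <- lapply(imgs, function(m) m * diff(rng) + rng[1])
    truth <- js
  }
  st <- slice_stack(imgs, msks, pixel_size, thickness)
  attr(st, "truth") <- truth
  st
}

#' Write a tissue mask as PNG (0/255)
#' @param mask a `tissue_mask` or 0/1 matrix.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "tissue_mask")) mask$mask else mask
  png::writePNG(m, path)
  invisible(path)
}
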