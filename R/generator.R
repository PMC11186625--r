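# Domain-randomized generative model for label-conditioned synthetic
# training images: spatial augmentation with a coronal deformation jitter,
# a conditional Gaussian mixture renderer with randomized per-label means
# and variances, digital slicing to a random (and within-stack varying)
# thickness, per-slice bias field and intensity transforms, and
# resampling back to the isotropic grid. Each draw yields an (image,
# label) training pair; the appearance randomization is deliberately
# wider than realistic so downstream models become contrast-agnostic.

#' Generator configuration
#'
#' @param labels integer vector of the label ids the generator must know.
#' @param mean_range,var_range per-label Gaussian parameter ranges; either
#'   a length-2 vector shared by all labels or a `length(labels) x 2`
#'   matrix. A (mean, variance) pair is drawn per label per call.
#' @param intensity_max clamp ceiling for rendered intensities.
#' @param deform_amplitude max displacement of the smooth 3D deformation
#'   field, mm.
#' @param deform_smoothness control-point spacing of the field, voxels.
#' @param jitter_amplitude max in-plane translation of the per-coronal-slab
#'   deformation jitter, mm.
#' @param jitter_rotation max in-plane rotation of the jitter, degrees.
#' @param thickness_range slice thickness sampling range, mm.
#' @param thickness_jitter within-stack per-slice variation of the cut
#'   position, in slices.
#' @param bias_amplitude max `|log|` of the per-slice multiplicative bias
#'   field (0 disables).
#' @param bias_smoothness control-point spacing of the bias field, px.
#' @param brightness_range,contrast_range,gamma_range intensity transform
#'   ranges; the transform is `((I * c + b) clipped to [0, max])^gamma`
#'   applied on the `[0, 1]`-normalized image.
#' @param resolution isotropic output resolution, mm.
#' @param seed integer seed.
#' @return object of class `gen_config`.
#' @export
gen_config <- function(labels,
                       mean_range = c(20, 230), var_range = c(0, 100),
                       intensity_max = 255,
                       deform_amplitude = 2, deform_smoothness = 10,
                       jitter_amplitude = 0.5, jitter_rotation = 1,
                       thickness_range = c(2, 8), thickness_jitter = 0.1,
                       bias_amplitude = 0.3, bias_smoothness = 16,
                       brightness_range = c(-0.1, 0.1),
                       contrast_range = c(0.8, 1.2),
                       gamma_range = c(0.8, 1.25),
                       resolution = 1, seed = 1L) {
  as_mat <- function(x) {
    if (is.matrix(x)) x else matrix(rep(x, each = length(labels)),
                                    length(labels), 2)
  }
  mean_range <- as_mat(mean_range); var_range <- as_mat(var_range)
  stopifnot(all(mean_range[, 1] <= mean_range[, 2]),
            all(var_range[, 1] <= var_range[, 2]),
            all(var_range >= 0), resolution > 0,
            thickness_range[1] <= thickness_range[2],
            deform_amplitude >= 0, jitter_amplitude >= 0,
            bias_amplitude >= 0)
  structure(list(labels = as.integer(labels),
                 mean_range = mean_range, var_range = var_range,
                 intensity_max = intensity_max,
                 deform_amplitude = deform_amplitude,
                 deform_smoothness = deform_smoothness,
                 jitter_amplitude = jitter_amplitude,
                 jitter_rotation = jitter_rotation,
                 thickness_range = thickness_range,
                 thickness_jitter = thickness_jitter,
                 bias_amplitude = bias_amplitude,
                 bias_smoothness = bias_smoothness,
                 brightness_range = brightness_range,
                 contrast_range = contrast_range,
                 gamma_range = gamma_range,
                 resolution = resolution, seed = as.integer(seed)),
            class = "gen_config")
}

#' Spatially augment a label volume
#'
#' A smooth random 3D deformation plus a small independent in-plane rigid
#' perturbation per coronal slab (the deformation jitter emulating
#' imperfect 3D reconstruction: abrupt changes from one coronal plane to
#' the next). Labels are resampled nearest-neighbour, so the label set can
#' only shrink, never grow. Zero amplitudes return the input unchanged.
#'
#' @param labels integer 3D label array.
#' @param cfg a [gen_config()].
#' @param voxel_size voxel size of `labels`, mm.
#' @param seed optional seed overriding `cfg$seed`.
#' @return list with `labels` (deformed array) and `field`
#'   (`H x W x D x 3` displacement field in voxels, for introspection).
#' @export
deform_labels <- function(labels, cfg, voxel_size = 1, seed = cfg$seed) {
  d <- dim(labels)
  if (cfg$deform_amplitude == 0 && cfg$jitter_amplitude == 0 &&
      cfg$jitter_rotation == 0)
    return(list(labels = labels, field = array(0, c(d, 3))))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  amp_vox <- cfg$deform_amplitude / voxel_size
  field <- array(0, c(d, 3))
  if (cfg$deform_amplitude > 0) {
    for (k in 1:3) {
      f <- smooth_noise_field(d, cfg$deform_smoothness)
      f <- f / max(abs(f), 1e-12) * amp_vox
      field[, , , k] <- f
    }
  }
  # per-coronal-slab (3rd axis) in-plane rigid jitter
  if (cfg$jitter_amplitude > 0 || cfg$jitter_rotation > 0) {
    cy <- (d[1] + 1) / 2; cx <- (d[2] + 1) / 2
    iy <- matrix(rep(seq_len(d[1]), d[2]), d[1], d[2]) - cy
    ix <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2]) - cx
    for (sl in seq_len(d[3])) {
      tj <- stats::runif(2, -cfg$jitter_amplitude, cfg$jitter_amplitude) / voxel_size
      aj <- stats::runif(1, -cfg$jitter_rotation, cfg$jitter_rotation) * pi / 180
      # displacement of a small in-plane rotation + translation
      field[, , sl, 1] <- field[, , sl, 1] +
        (cos(aj) - 1) * iy - sin(aj) * ix + tj[1]
      field[, , sl, 2] <- field[, , sl, 2] +
        sin(aj) * iy + (cos(aj) - 1) * ix + tj[2]
    }
  }
  iy <- array(rep(seq_len(d[1]), d[2] * d[3]), d)
  ix <- array(rep(rep(seq_len(d[2]), each = d[1]), d[3]), d)
  iz <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  out <- interp3_nn(labels, ix + field[, , , 2], iy + field[, , , 1],
                    iz + field[, , , 3])
  storage.mode(out) <- "integer"
  list(labels = out, field = field)
}

#' Render a synthetic intensity volume from a label map
#'
#' Draws one (mean, variance) pair per label from the configured ranges,
#' then samples every voxel independently from its label's univariate
#' Gaussian, clamping to `[0, intensity_max]`. The drawn parameters are
#' returned for testability.
#'
#' @param labels integer 3D label array; every present label must appear
#'   in `cfg$labels`.
#' @param cfg a [gen_config()].
#' @param seed optional seed overriding `cfg$seed`.
#' @return list with `image` and `params` (tibble: label, mean, var).
#' @export
gmm_render <- function(labels, cfg, seed = cfg$seed) {
  present <- sort(unique(as.vector(labels)))
  present <- present[present != 0]
  missing <- setdiff(present, cfg$labels)
  if (length(missing))
    stop("MissingLabelParams: no Gaussian ranges for label(s) ",
         paste(missing, collapse = ", "))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  kk <- length(cfg$labels)
  mu <- stats::runif(kk, cfg$mean_range[, 1], cfg$mean_range[, 2])
  va <- stats::runif(kk, cfg$var_range[, 1], cfg$var_range[, 2])
  img <- array(0, dim(labels))
  for (i in seq_len(kk)) {
    l <- cfg$labels[i]
    sel <- labels == l
    nsel <- sum(sel)
    if (nsel)
      img[sel] <- stats::rnorm(nsel, mu[i], sqrt(va[i]))
  }
  img[img < 0] <- 0
  img[img > cfg$intensity_max] <- cfg$intensity_max
  list(image = img,
       params = tibble::tibble(label = cfg$labels, mean = mu, var = va))
}

#' Simulate one training pair of the generative model
#'
#' The full pipeline: spatial augmentation of the label map (smooth
#' deformation + coronal jitter), Gaussian-mixture rendering with
#' randomized per-label appearance, digital slicing to a random thickness
#' with small per-slice thickness variation, per-slice multiplicative
#' bias field and brightness/contrast/gamma augmentation, and resampling
#' back to the isotropic output grid. The target is the deformed label
#' map on the same grid.
#'
#' @param labels integer 3D label array at `cfg$resolution`.
#' @param cfg a [gen_config()].
#' @param seed optional seed overriding `cfg$seed`.
#' @return list with `image`, `target` (same shape), `thickness` (mm) and
#'   `gmm_params`.
#' @export
simulate_training_pair <- function(labels, cfg, seed = cfg$seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  def <- deform_labels(labels, cfg, voxel_size = cfg$resolution,
                       seed = seed + 1L)
  rend <- gmm_render(def$labels, cfg, seed = seed + 2L)
  img <- rend$image
  d <- dim(img)

  thick <- stats::runif(1, cfg$thickness_range[1], cfg$thickness_range[2])
  step <- thick / cfg$resolution                 # slice period in voxels
  n_sl <- max(2L, floor((d[3] - 1) / step) + 1L)
  centres <- 1 + (seq_len(n_sl) - 1) * step
  if (cfg$thickness_jitter > 0)
    centres <- centres +
      stats::runif(n_sl, -cfg$thickness_jitter, cfg$thickness_jitter) * step
  centres <- pmin(pmax(centres, 1), d[3])

  # partial-volume extraction: average the volume over each slice's slab
  low <- array(0, c(d[1], d[2], n_sl))
  half <- max(step / 2, 0.5)
  for (n in seq_len(n_sl)) {
    zs <- seq(centres[n] - half + 0.5, centres[n] + half - 0.5,
              length.out = max(1L, ceiling(step)))
    zs <- pmin(pmax(zs, 1), d[3])
    acc <- 0
    for (z in zs) {
      z0 <- floor(z); fz <- z - z0
      z1 <- min(z0 + 1L, d[3])
      acc <- acc + img[, , z0] * (1 - fz) + img[, , z1] * fz
    }
    sl <- acc / length(zs)
    if (cfg$bias_amplitude > 0) {
      b <- smooth_noise_field(d[1:2], cfg$bias_smoothness)
      b <- b / max(abs(b), 1e-12) * cfg$bias_amplitude
      sl <- sl * exp(b)
    }
    br <- stats::runif(1, cfg$brightness_range[1], cfg$brightness_range[2])
    co <- stats::runif(1, cfg$contrast_range[1], cfg$contrast_range[2])
    ga <- stats::runif(1, cfg$gamma_range[1], cfg$gamma_range[2])
    sln <- sl / cfg$intensity_max
    sln <- pmin(pmax(sln * co + br, 0), 1)^ga
    low[, , n] <- sln * cfg$intensity_max
  }

  # resample the anisotropic stack back to the isotropic grid (linear
  # interpolation between slice centres along the slicing axis)
  out <- array(0, d)
  pos <- centres
  for (z in seq_len(d[3])) {
    i <- findInterval(z, pos, all.inside = TRUE)
    z0 <- pos[i]; z1 <- pos[min(i + 1L, n_sl)]
    f <- if (z1 > z0) (z - z0) / (z1 - z0) else 0
    f <- min(max(f, 0), 1)
    out[, , z] <- low[, , i] * (1 - f) + low[, , min(i + 1L, n_sl)] * f
  }
  list(image = out, target = def$labels, thickness = thick,
       gmm_params = rend$params)
}
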