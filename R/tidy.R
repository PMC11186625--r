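# Broom-style summaries and ggplot2 views of reconstruction results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-slice transforms of a reconstruction
#'
#' One row per slice with the planar transform parameters (translations in
#' mm, rotation in degrees, log-scales and shear for affine transforms)
#' and the log-determinant regularizer value.
#'
#' @param x a `recon_result`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.recon_result <- function(x, ...) {
  n <- length(x$params$phi)
  affine <- length(x$params$phi[[1]]) == 6
  rows <- lapply(seq_len(n), function(i) {
    th <- x$params$phi[[i]]
    tibble::tibble(
      slice = i,
      tx_mm = th[1], ty_mm = th[2], rotation_deg = th[3] * 180 / pi,
      log_scale_1 = if (affine) th[4] else 0,
      log_scale_2 = if (affine) th[5] else 0,
      shear = if (affine) th[6] else 0,
      log_det_penalty = if (affine) abs(th[4] + th[5]) else 0)
  })
  do.call(rbind, rows)
}

#' One-row summary of a reconstruction
#'
#' @param x a `recon_result`.
#' @param ... unused.
#' @return tibble with the mode, slice count, final objective value,
#'   anterior-posterior scale and convergence flag.
#' @export
glance.recon_result <- function(x, ...) {
  tibble::tibble(mode = x$mode,
                 n_slices = length(x$params$phi),
                 objective = utils::tail(x$objective_trace, 1),
                 s = x$params$s,
                 iterations = length(x$objective_trace),
                 converged = x$converged)
}

#' Plot the objective trace of a reconstruction
#'
#' @param object a `recon_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.recon_result <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$objective_trace),
                       objective = object$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "outer L-BFGS iteration", y = "objective F") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Box plot of reconstruction errors by spacing and jitter
#'
#' The standard view of a digital-slicing experiment: per-condition box
#' plots of the mean voxel displacement.
#'
#' @param errors data frame with columns `spacing`, `jitter`, `error_mm`.
#' @return a ggplot.
#' @export
plot_error_box <- function(errors) {
  stopifnot(all(c("spacing", "jitter", "error_mm") %in% names(errors)))
  ggplot2::ggplot(errors,
                  ggplot2::aes(x = factor(.data$spacing),
                               y = .data$error_mm,
                               fill = factor(.data$jitter))) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::labs(x = "slice spacing (voxels)", y = "reconstruction error (mm)",
                  fill = "thickness jitter") +
    ggplot2::theme_minimal()
}

#' Display a coronal slab of a reconstructed volume
#'
#' @param result a `recon_result`.
#' @param slab slab index (defaults to the middle).
#' @return a ggplot raster view.
#' @export
plot_slab <- function(result, slab = NULL) {
  v <- result$volume$image
  if (is.null(slab)) slab <- ceiling(dim(v)[3] / 2)
  m <- v[, , slab]
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$intensity <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() + ggplot2::theme_void() +
    ggplot2::labs(fill = "intensity")
}

#' @importFrom rlang .data
NULL
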