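# Joint reconstruction: initialization, multi-resolution L-BFGS driver,
# result container.

#' Initialize reconstruction parameters
#'
#' Centre-of-gravity initialization: each slice transform is the pure
#' translation that moves the centroid of its tissue mask to in-plane
#' coordinate (0, 0); the anterior-posterior scale starts at 1; the
#' reference transform is the translation matching the centroid of the
#' reference with the centroid of the centred stack. No rotation, scaling
#' or shear is introduced at this stage.
#'
#' @param stack a [slice_stack()].
#' @param ref a [reference_volume()].
#' @param mode `"surface"` (affine slice transforms, rigid reference
#'   transform, free scale) or `"atlas"` (rigid slice transforms, affine
#'   reference transform, scale fixed to 1).
#' @return an object of class `recon_params` with elements `phi` (list of
#'   per-slice parameter vectors), `s`, `psi`, `mode`.
#' @export
init_params <- function(stack, ref, mode = c("surface", "atlas")) {
  mode <- match.arg(mode)
  N <- stack$n
  g <- grid_mm(dim(stack$masks)[1], dim(stack$masks)[2], stack$pixel_size)
  npp <- if (mode == "surface") 6L else 3L
  phi <- vector("list", N)
  wts <- numeric(N)
  for (n in seq_len(N)) {
    m <- stack$masks[, , n]
    tot <- sum(m)
    if (tot == 0) stop(sprintf("EmptySliceMask: slice %d has an empty mask", n))
    cx <- sum(m * g$X) / tot; cy <- sum(m * g$Y) / tot
    th <- numeric(npp)
    th[1] <- -cx; th[2] <- -cy
    phi[[n]] <- th
    wts[n] <- tot
  }
  z <- slab_z(N, 1, stack$thickness)
  c_stack <- c(0, 0, sum(wts * z) / sum(wts))
  c_ref <- ref_centroid_mm(ref)
  psi <- if (mode == "surface") {
    c(c_ref - c_stack, 0, 0, 0)
  } else {
    c(as.vector(diag(3)), c_ref - c_stack)
  }
  structure(list(phi = phi, s = 1, psi = psi, mode = mode),
            class = "recon_params")
}

#' @export
print.recon_params <- function(x, ...) {
  cat(sprintf("<recon_params> %s mode, %d slice transforms, s = %.4f\n",
              x$mode, length(x$phi), x$s))
  invisible(x)
}

# Padded common in-plane grid: 1.2x the largest slice mask bounding box so
# optimized transforms cannot push tissue off-grid.
padded_grid <- function(stack, factor = 1.2) {
  d <- dim(stack$masks)
  any_m <- apply(stack$masks > 0, c(1, 2), any)
  rows <- range(which(rowSums(any_m) > 0))
  cols <- range(which(colSums(any_m) > 0))
  h <- ceiling((rows[2] - rows[1] + 1) * factor)
  w <- ceiling((cols[2] - cols[1] + 1) * factor)
  c(min(max(h, 8), d[1] * 2), min(max(w, 8), d[2] * 2))
}

# Half-resolution copies for the coarse pyramid level.
downsample_stack <- function(stack) {
  imgs <- apply(stack$images, 3, block_mean, simplify = FALSE)
  msks <- apply(stack$masks, 3, block_mean, simplify = FALSE)
  slice_stack(imgs, msks, stack$pixel_size * 2, stack$thickness)
}

downsample_reference <- function(ref) {
  v <- block_mean(ref$volume)
  if (ref$kind == "surface_mask") {
    reference_volume((v >= 0.5) * 1, ref$voxel_size * 2, ref$kind, ref$origin)
  } else {
    reference_volume(pmin(pmax(v, 0), 1), ref$voxel_size * 2, ref$kind,
                     ref$origin)
  }
}

#' Reconstruct a 3D volume from a photographed slice stack
#'
#' Jointly estimates the per-slice planar transforms, the
#' anterior-posterior scale and the reference pose by maximizing the
#' soft-Dice / NCC objective with L-BFGS, starting from the
#' centre-of-gravity initialization, optionally with a 2-level
#' coarse-to-fine pyramid.
#'
#' In `"surface"` mode the slice transforms are full planar affines, the
#' scale `s` is free and the reference transform is rigid; in `"atlas"`
#' mode the slice transforms are rigid, `s` is fixed to 1 exactly (the
#' user-specified thickness is trusted) and the reference transform is a
#' full 3D affine. The rigid slice transforms of atlas mode make the
#' log-determinant regularizer identically zero.
#'
#' @param stack a [slice_stack()].
#' @param ref a [reference_volume()]; its `kind` must match `mode`
#'   (`surface_mask` for `"surface"`, either kind for `"atlas"`).
#' @param mode `"surface"` or `"atlas"`.
#' @param weights an [objective_weights()] list.
#' @param opts list of optimizer options: `max_outer` (outer L-BFGS rounds,
#'   default 50), `inner_iter` (L-BFGS iterations per round, default 10),
#'   `tol` (`|dF|` convergence threshold, default 1e-6), `tol_iters`
#'   (consecutive converged rounds required, default 5), `pyramid`
#'   (coarse-to-fine, default TRUE), `pad_factor` (grid padding, default
#'   1.2).
#' @return object of class `recon_result`: `params`, `volume` (assembled
#'   [assemble()] output), `objective_trace`, `converged`, `weights`,
#'   `mode`.
#' @export
reconstruct <- function(stack, ref, mode = c("surface", "atlas"),
                        weights = NULL, opts = list()) {
  mode <- match.arg(mode)
  if (mode == "surface" && ref$kind != "surface_mask")
    stop("surface mode requires a surface_mask reference")
  if (is.null(weights)) weights <- objective_weights(mode)
  o <- utils::modifyList(list(max_outer = 5L, inner_iter = 100L, tol = 1e-6,
                              tol_iters = 2L, pyramid = TRUE,
                              pad_factor = 1.2, ref_blur = 0,
                              alpha_form = "mass",
                              slab_subsamples = 3L), opts)
  # optional softening of the reference during optimization only
  ref_opt <- if (o$ref_blur > 0) {
    rb <- pmin(pmax(blur3(ref$volume, o$ref_blur), 0), 1)
    reference_volume(rb, ref$voxel_size, "probabilistic_atlas", ref$origin)
  } else ref

  out_hw <- padded_grid(stack, o$pad_factor)
  par <- pack_params(init_params(stack, ref, mode))
  trace <- numeric(0)

  run_level <- function(stk, rf, hw, par, max_outer) {
    cache <- new.env(parent = emptyenv())
    eval_at <- function(p) {
      key <- cache$par
      if (!is.null(key) && identical(key, p)) return(cache$res)
      res <- objective_core(stk, p, rf, weights, mode, hw, grad = TRUE,
                            alpha_form = o$alpha_form,
                            slab_subsamples = o$slab_subsamples)
      cache$par <- p; cache$res <- res
      res
    }
    fn <- function(p) -eval_at(p)$F
    gr <- function(p) -eval_at(p)$grad
    tr <- numeric(0)
    ok <- 0L
    fprev <- eval_at(par)$F
    for (it in seq_len(max_outer)) {
      op <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                         control = list(maxit = o$inner_iter, lmm = 10,
                                        factr = 1e7))
      par <- op$par
      fcur <- -op$value
      tr <- c(tr, fcur)
      if (abs(fcur - fprev) < o$tol) ok <- ok + 1L else ok <- 0L
      fprev <- fcur
      if (ok >= o$tol_iters) break
    }
    list(par = par, trace = tr, converged = ok >= o$tol_iters)
  }

  converged <- FALSE
  if (isTRUE(o$pyramid) && all(dim(stack$images)[1:2] >= 16) &&
      all(dim(ref$volume) >= 8)) {
    stk2 <- downsample_stack(stack)
    ref2 <- downsample_reference(ref_opt)
    hw2 <- pmax(out_hw %/% 2L, 8L)
    lev <- run_level(stk2, ref2, hw2, par, max_outer = o$max_outer)
    par <- lev$par
    trace <- c(trace, lev$trace)
  }
  lev <- run_level(stack, ref_opt, out_hw, par, max_outer = o$max_outer)
  par <- lev$par
  trace <- c(trace, lev$trace)
  converged <- lev$converged

  params <- unpack_params(par, stack$n, mode)
  structure(list(params = params,
                 volume = assemble(stack, params, out_hw),
                 objective_trace = trace,
                 converged = converged,
                 weights = weights, mode = mode,
                 out_hw = out_hw),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf(
    "<recon_result> %s mode, %d slices, s = %.4f, F = %.5f (%s)\n",
    x$mode, length(x$params$phi), x$params$s,
    utils::tail(x$objective_trace, 1),
    if (x$converged) "converged" else "max iterations"))
  invisible(x)
}
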