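# The joint registration objective
#
#   F = alpha * D(M, R o Psi)
#     + beta  * mean_n C(S_n, S_{n+1})
#     + gamma * mean_n D(M_n, M_{n+1})
#     - nu    * mean_n f(Phi_n)
#
# where D is the soft Dice coefficient, C a (mask-weighted) normalized
# cross-correlation between consecutive resampled slices, and f the
# absolute log-determinant of the planar linear part. All terms are
# computed on the common voxel grid of the assembled stack; the reference
# is pulled onto that grid through Psi by linear interpolation. The whole
# objective is differentiable in the slice transforms, the
# anterior-posterior scale and the reference transform, and the analytic
# gradient is used by the L-BFGS optimizer.

DICE_EPS <- 1e-6

#' Soft Dice coefficient
#'
#' `2 * sum(a*b) / (sum(a) + sum(b) + eps)` for soft masks in `[0, 1]`.
#' Symmetric and differentiable; returns 0 when both inputs are all-zero.
#'
#' @param a,b numeric arrays of identical shape with values in `[0, 1]`.
#' @param eps stabilizer added to the denominator.
#' @return scalar in `[0, 1]`.
#' @export
#' @examples
#' a <- array(0, c(2, 2, 2)); a[1:2, 1:2, 1] <- 1
#' soft_dice(a, a)  # ~1
soft_dice <- function(a, b, eps = DICE_EPS) {
  stopifnot(identical(dim_or_len(a), dim_or_len(b)))
  2 * sum(a * b) / (sum(a) + sum(b) + eps)
}

#' Normalized cross-correlation over a support region
#'
#' Pearson-type correlation of two images restricted to (or weighted by) a
#' support region. Returns 0 (neutral) if either side has zero variance on
#' the support.
#'
#' @param a,b numeric arrays of identical shape.
#' @param support binary or soft weights of the same shape; defaults to the
#'   full domain.
#' @return scalar in `[-1, 1]`.
#' @export
ncc <- function(a, b, support = NULL) {
  stopifnot(identical(dim_or_len(a), dim_or_len(b)))
  if (is.null(support)) support <- array(1, dim_or_len(a))
  wncc_grad(a, b, support, grad = FALSE)$C
}

# Weighted NCC with optional analytic gradients with respect to a, b and
# the weights w. Means and variances are w-weighted.
wncc_grad <- function(a, b, w, grad = TRUE) {
  W <- sum(w)
  zero <- function() {
    out <- list(C = 0)
    if (grad) { z <- array(0, dim_or_len(a)); out$da <- z; out$db <- z; out$dw <- z }
    out
  }
  if (W <= .Machine$double.eps) return(zero())
  am <- sum(w * a) / W; bm <- sum(w * b) / W
  A0 <- a - am; B0 <- b - bm
  Saa <- sum(w * A0 * A0); Sbb <- sum(w * B0 * B0); Sab <- sum(w * A0 * B0)
  if (Saa <= 1e-12 || Sbb <= 1e-12) return(zero())
  den <- sqrt(Saa * Sbb)
  C <- Sab / den
  out <- list(C = C)
  if (grad) {
    out$da <- (w * B0) / den - C * (w * A0) / Saa
    out$db <- (w * A0) / den - C * (w * B0) / Sbb
    out$dw <- (A0 * B0) / den - (C / 2) * (A0 * A0 / Saa + B0 * B0 / Sbb)
  }
  out
}

#' Objective weights
#'
#' Relative weights of the four terms of the registration objective. The
#' defaults depend on the reference: with a case-specific surface scan the
#' overlap term dominates; with a population atlas the reference is
#' trusted less and regularization is stronger.
#'
#' @param mode `"surface"` or `"atlas"`.
#' @param alpha,beta,gamma,nu optional overrides (all non-negative).
#' @return list with elements `alpha`, `beta`, `gamma`, `nu`.
#' @export
objective_weights <- function(mode = c("surface", "atlas"),
                              alpha = NULL, beta = NULL, gamma = NULL,
                              nu = NULL) {
  mode <- match.arg(mode)
  w <- if (mode == "surface") {
    list(alpha = 0.95, beta = 0.025, gamma = 0.025, nu = 0.025 / 100)
  } else {
    list(alpha = 0.8, beta = 0.1, gamma = 0.1, nu = 0.1)
  }
  if (!is.null(alpha)) w$alpha <- alpha
  if (!is.null(beta)) w$beta <- beta
  if (!is.null(gamma)) w$gamma <- gamma
  if (!is.null(nu)) w$nu <- nu
  stopifnot(all(unlist(w) >= 0))
  w
}

# --- parameter vector packing -----------------------------------------------
# surface mode: par = c(sigma, psi[6 rigid], theta_1[6], ..., theta_N[6])
#               with s = exp(sigma), affine per-slice transforms
# atlas mode:   par = c(psi[12 affine], theta_1[3], ..., theta_N[3])
#               with s fixed to 1, rigid per-slice transforms

pack_params <- function(params) {
  if (params$mode == "surface") {
    c(log(params$s), params$psi, unlist(params$phi))
  } else {
    c(params$psi, unlist(params$phi))
  }
}

unpack_params <- function(par, n_slices, mode) {
  if (mode == "surface") {
    s <- exp(par[1])
    psi <- par[2:7]
    k <- 6
    phi <- lapply(seq_len(n_slices),
                  function(n) par[7 + (n - 1) * k + seq_len(k)])
  } else {
    s <- 1
    psi <- par[1:12]
    k <- 3
    phi <- lapply(seq_len(n_slices),
                  function(n) par[12 + (n - 1) * k + seq_len(k)])
  }
  structure(list(phi = phi, s = s, psi = psi, mode = mode),
            class = "recon_params")
}

# --- the objective and its gradient -----------------------------------------

# Core evaluation. Returns list(F, grad (if requested), terms).
objective_core <- function(stack, par, ref, weights, mode,
                           out_hw = dim(stack$images)[1:2], grad = TRUE,
                           alpha_form = c("mass", "plain"),
                           slab_subsamples = 1L) {
  alpha_form <- match.arg(alpha_form)
  N <- stack$n
  p <- stack$pixel_size
  prm <- unpack_params(par, N, mode)
  npp <- if (mode == "surface") 6L else 3L  # params per slice

  # resample all slices (images + masks) with per-parameter derivatives
  S <- vector("list", N); M <- vector("list", N)
  src_hw <- dim(stack$images)[1:2]
  for (n in seq_len(N)) {
    rs <- resample_slice_multi(list(stack$images[, , n], stack$masks[, , n]),
                               prm$phi[[n]], p, src_hw, out_hw, grad)
    S[[n]] <- rs[[1]]; M[[n]] <- rs[[2]]
  }

  g <- grid_mm(out_hw[1], out_hw[2], p)
  z <- slab_z(N, prm$s, stack$thickness)

  # pull the reference onto the stack grid through psi. With
  # slab_subsamples = 1 the reference is sampled at the slab centre plane
  # (the plain reading of the objective). With k > 1 it is averaged over
  # the slab thickness (k-point midpoint rule along the slicing axis,
  # each slab being s * thickness mm thick); a stretched stack then
  # dilutes its slab averages where they overrun the reference, which is
  # what identifies the anterior-posterior scale during optimization.
  pm <- psi_matrix(prm$psi)
  L <- pm$L; tt <- pm$t
  HW <- prod(out_hw)
  nsub <- as.integer(slab_subsamples)
  zoff <- (seq_len(nsub) - (nsub + 1) / 2) / nsub * prm$s * stack$thickness
  Rhat <- array(0, c(out_hw, N))
  sub <- if (grad) vector("list", N * nsub) else NULL
  for (n in seq_len(N)) {
    for (j in seq_len(nsub)) {
      zj <- z[n] + zoff[j]
      qx <- L[1, 1] * g$X + L[1, 2] * g$Y + L[1, 3] * zj + tt[1]
      qy <- L[2, 1] * g$X + L[2, 2] * g$Y + L[2, 3] * zj + tt[2]
      qz <- L[3, 1] * g$X + L[3, 2] * g$Y + L[3, 3] * zj + tt[3]
      idx <- ref_mm_to_idx(ref, qx, qy, qz)
      it <- interp3(ref$volume, idx$x, idx$y, idx$z, grad = grad,
                    kernel = "smooth")
      Rhat[, , n] <- Rhat[, , n] + it$v / nsub
      if (grad) {
        sub[[(n - 1) * nsub + j]] <- list(
          gx = it$dx / ref$voxel_size[1],
          gy = it$dy / ref$voxel_size[2],
          gz = it$dz / ref$voxel_size[3],
          zj = zj)
      }
    }
  }

  Mvol <- array(0, c(out_hw, N))
  for (n in seq_len(N)) Mvol[, , n] <- M[[n]]$v

  # alpha: soft Dice between the assembled mask stack and the reference,
  # evaluated in physical (mm^3) units over all space: the intersection is
  # integrated on the stack grid (the only place M is nonzero), while the
  # reference volume in the denominator is its invariant total mass under
  # the current pose. Reference mass outside the stack's extent therefore
  # still counts, which is what penalizes contracting the stack (in-plane
  # or along the slicing axis) to inflate the sampled overlap, while the
  # slab averaging above penalizes stretching it.
  P <- sum(Mvol * Rhat); Q <- sum(Mvol)
  if (alpha_form == "mass") {
    vcell <- p^2 * prm$s * stack$thickness         # stack grid cell, mm^3
    detL <- abs(det(L))
    Vref <- sum(ref$volume) * prod(ref$voxel_size) / detL
    num <- 2 * vcell * P; den <- vcell * Q + Vref + DICE_EPS
  } else {
    vcell <- 1
    num <- 2 * P; den <- Q + sum(Rhat) + DICE_EPS
  }
  D_alpha <- num / den

  # beta / gamma: consecutive-slice similarity and overlap
  Cs <- numeric(N - 1); Ds <- numeric(N - 1)
  pair_cache <- vector("list", N - 1)
  for (n in seq_len(N - 1)) {
    a <- S[[n]]$v; b <- S[[n + 1]]$v
    ma <- M[[n]]$v; mb <- M[[n + 1]]$v
    w <- ma + mb - ma * mb  # soft union support
    wn <- wncc_grad(a, b, w, grad = grad)
    Cs[n] <- wn$C
    dn <- sum(ma) + sum(mb) + DICE_EPS
    nn <- 2 * sum(ma * mb)
    Ds[n] <- nn / dn
    if (grad) pair_cache[[n]] <- list(wn = wn, dn = dn, nn = nn)
  }
  beta_term <- mean(Cs); gamma_term <- mean(Ds)

  # nu: log-determinant regularizer (identically zero for rigid transforms)
  fs <- vapply(prm$phi, function(th)
    if (length(th) == 6) abs(th[4] + th[5]) else 0, numeric(1))
  nu_term <- mean(fs)

  Fval <- weights$alpha * D_alpha + weights$beta * beta_term +
    weights$gamma * gamma_term - weights$nu * nu_term

  out <- list(F = Fval,
              terms = list(dice_ref = D_alpha, ncc_pairs = beta_term,
                           dice_pairs = gamma_term, regularizer = nu_term))
  if (!grad) return(out)

  gvec <- numeric(length(par))

  # d(alpha)/dRhat channel -> psi (and sigma in surface mode), accumulated
  # over the slab sub-samples
  dD_dR <- if (alpha_form == "mass") (2 * vcell * Mvol) / den
           else (2 * Mvol) / den - num / den^2
  pg <- psi_matrix_grad(prm$psi)
  mom <- matrix(0, 3, 3)  # mom[a, b] = sum over samples of G_a * x_b
  gsum <- c(0, 0, 0)
  sig_pos <- 0            # position channel of the sigma gradient
  for (n in seq_len(N)) {
    w2 <- dD_dR[, , n] / nsub
    for (j in seq_len(nsub)) {
      sb <- sub[[(n - 1) * nsub + j]]
      Gx2 <- w2 * sb$gx; Gy2 <- w2 * sb$gy; Gz2 <- w2 * sb$gz
      sx <- sum(Gx2); sy <- sum(Gy2); sz <- sum(Gz2)
      mom[1, ] <- mom[1, ] + c(sum(Gx2 * g$X), sum(Gx2 * g$Y), sx * sb$zj)
      mom[2, ] <- mom[2, ] + c(sum(Gy2 * g$X), sum(Gy2 * g$Y), sy * sb$zj)
      mom[3, ] <- mom[3, ] + c(sum(Gz2 * g$X), sum(Gz2 * g$Y), sz * sb$zj)
      gsum <- gsum + c(sx, sy, sz)
      sig_pos <- sig_pos + sb$zj * (L[1, 3] * sx + L[2, 3] * sy + L[3, 3] * sz)
    }
  }
  psi_idx <- if (mode == "surface") 1 + seq_len(6) else seq_len(12)
  for (k in seq_along(psi_idx)) {
    gvec[psi_idx[k]] <- weights$alpha *
      (sum(pg$dL[[k]] * mom) + sum(pg$dt[[k]] * gsum))
  }
  if (mode == "atlas" && alpha_form == "mass") {
    # the reference's total mass shrinks as the affine linear part grows:
    # d|det L|/dL = |det L| (L^-1)^T, so dVref/dL = -Vref (L^-1)^T
    Linv <- solve(L)
    for (k in seq_len(9)) {
      a <- (k - 1) %% 3 + 1; b <- (k - 1) %/% 3 + 1
      gvec[k] <- gvec[k] + weights$alpha * num * Vref * Linv[b, a] / den^2
    }
  }
  if (mode == "surface") {
    # sample positions z_n + zoff_j are proportional to s = exp(sigma); in
    # the mass form the cell volume scales with s as well
    gvec[1] <- weights$alpha * sig_pos
    if (alpha_form == "mass")
      gvec[1] <- gvec[1] + weights$alpha * D_alpha * (1 - vcell * Q / den)
  }

  # dD_alpha/dM channel (voxelwise) feeds per-slice transforms below
  dD_dM <- (2 * vcell * Rhat) / den - num * vcell / den^2

  off0 <- if (mode == "surface") 7L else 12L
  for (n in seq_len(N)) {
    acc_img <- array(0, out_hw)  # dF/d Shat_n
    acc_msk <- dD_dM[, , n] * weights$alpha  # dF/d Mhat_n
    if (n > 1) {
      pc <- pair_cache[[n - 1]]
      acc_img <- acc_img + (weights$beta / (N - 1)) * pc$wn$db
      ma <- M[[n - 1]]$v
      acc_msk <- acc_msk + (weights$beta / (N - 1)) * pc$wn$dw * (1 - ma) +
        (weights$gamma / (N - 1)) * (2 * ma / pc$dn - pc$nn / pc$dn^2)
    }
    if (n < N) {
      pc <- pair_cache[[n]]
      acc_img <- acc_img + (weights$beta / (N - 1)) * pc$wn$da
      mb <- M[[n + 1]]$v
      acc_msk <- acc_msk + (weights$beta / (N - 1)) * pc$wn$dw * (1 - mb) +
        (weights$gamma / (N - 1)) * (2 * mb / pc$dn - pc$nn / pc$dn^2)
    }
    idx <- off0 + (n - 1) * npp
    for (k in seq_len(npp)) {
      gvec[idx + k] <- sum(acc_img * S[[n]]$dtheta[[k]]) +
        sum(acc_msk * M[[n]]$dtheta[[k]])
    }
    if (npp == 6) {
      sgn <- sign(prm$phi[[n]][4] + prm$phi[[n]][5])
      gvec[idx + 4] <- gvec[idx + 4] - weights$nu / N * sgn
      gvec[idx + 5] <- gvec[idx + 5] - weights$nu / N * sgn
    }
  }

  out$grad <- gvec
  out
}

#' Evaluate the registration objective
#'
#' Computes the value of the joint slice-to-volume objective for a given
#' stack, parameter set and reference.
#'
#' @param stack a [slice_stack()].
#' @param params a `recon_params` object (e.g. from [init_params()]).
#' @param ref a [reference_volume()].
#' @param weights an [objective_weights()] list.
#' @param out_hw in-plane grid shape on which terms are evaluated.
#' @return scalar objective value `F`; the per-term breakdown is attached
#'   as attribute `"terms"`.
#' @export
objective <- function(stack, params, ref,
                      weights = objective_weights(params$mode),
                      out_hw = dim(stack$images)[1:2]) {
  res <- objective_core(stack, pack_params(params), ref, weights,
                        params$mode, out_hw, grad = FALSE)
  structure(res$F, terms = res$terms)
}
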