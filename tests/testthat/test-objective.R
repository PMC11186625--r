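# The registration objective and its building blocks.

test_that("soft_dice matches analytic values and a brute-force loop", {
  a <- array(0, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- 1   # 8-voxel cube
  b <- array(0, c(4, 4, 4)); b[1:2, 1:2, 1] <- 1     # 4-voxel half
  expect_equal(soft_dice(a, a), 1, tolerance = 1e-6)
  expect_equal(soft_dice(a, b), 2 * 4 / (8 + 4), tolerance = 1e-6)
  disj <- array(0, c(4, 4, 4)); disj[3:4, 3:4, 3:4] <- 1
  expect_equal(soft_dice(a, disj), 0)
  expect_equal(soft_dice(a * 0, a * 0), 0)  # all-zero convention
  # random soft masks against the loop oracle
  withr::with_seed(11, {
    for (i in 1:100) {
      u <- array(runif(125), c(5, 5, 5)); v <- array(runif(125), c(5, 5, 5))
      expect_equal(soft_dice(u, v), dice_loop(u, v), tolerance = 1e-10)
    }
  })
})

test_that("ncc matches Pearson correlation and handles degeneracies", {
  a <- matrix(1:16, 4, 4) / 16
  expect_equal(ncc(a, a), 1, tolerance = 1e-12)
  expect_equal(ncc(a, -a + 3), -1, tolerance = 1e-12)
  expect_equal(ncc(c(1, 2, 3, 4), c(1, 2, 4, 6)),
               cor(c(1, 2, 3, 4), c(1, 2, 4, 6)), tolerance = 1e-12)
  expect_equal(ncc(a, matrix(1, 4, 4)), 0)  # zero variance -> neutral
  withr::with_seed(12, {
    for (i in 1:100) {
      u <- array(runif(125), c(5, 5, 5)); v <- array(runif(125), c(5, 5, 5))
      w <- array(rbinom(125, 1, 0.7), c(5, 5, 5))
      expect_equal(ncc(u, v), ncc_loop(u, v), tolerance = 1e-10)
      expect_equal(ncc(u, v, support = w), ncc_loop(u, v, w),
                   tolerance = 1e-10)
    }
  })
})

test_that("affine_penalty is |log det| of the linear part", {
  expect_equal(affine_penalty(diag(3)), 0)
  rot <- phi_homogeneous(c(0, 0, 37 * pi / 180, 0, 0, 0))
  expect_equal(affine_penalty(rot), 0, tolerance = 1e-12)
  expect_equal(affine_penalty(c(0, 0, 0, log(2), log(2), 0)), abs(log(4)),
               tolerance = 1e-12)
  refl <- diag(3); refl[1, 1] <- -1
  expect_error(affine_penalty(refl), "SingularTransform")
})

test_that("a self-consistent stack attains the analytic extreme of F", {
  # identical slices, identity parameters, the stack's own assembled mask
  # as reference: every term attains its extreme, so F = alpha+beta+gamma
  H <- 14; W <- 14; N <- 6
  img <- matrix(0, H, W); img[4:10, 3:12] <- 0.5
  img[5:7, 5:8] <- 0.9
  msk <- (img > 0) * 1
  stack <- slice_stack(array(rep(img, N), c(H, W, N)),
                       array(rep(msk, N), c(H, W, N)),
                       pixel_size = 1, thickness = 2)
  params <- structure(list(phi = replicate(N, numeric(6), simplify = FALSE),
                           s = 1, psi = rep(0, 6), mode = "surface"),
                      class = "recon_params")
  vol <- assemble(stack, params)
  ref <- reference_volume(vol$mask, voxel_size = c(1, 1, 2), "surface_mask")
  w <- objective_weights("surface")
  expect_equal(w$alpha, 0.95)
  expect_equal(w$beta, 0.025)
  expect_equal(w$gamma, 0.025)
  expect_equal(w$nu, 0.025 / 100)
  Fv <- objective(stack, params, ref)
  expect_equal(as.numeric(Fv), w$alpha + w$beta + w$gamma, tolerance = 1e-4)

  # reference translated far away: overlap term collapses, others unchanged
  params2 <- params; params2$psi[1:3] <- c(500, 500, 500)
  F2 <- objective(stack, params2, ref)
  t1 <- attr(Fv, "terms"); t2 <- attr(F2, "terms")
  expect_lt(t2$dice_ref, 0.01)
  expect_equal(t2$ncc_pairs, t1$ncc_pairs, tolerance = 1e-12)
  expect_equal(t2$dice_pairs, t1$dice_pairs, tolerance = 1e-12)

  # nu = 0 makes the regularizer weightless regardless of slice scaling
  params3 <- params
  for (n in seq_len(N)) params3$phi[[n]][4:5] <- log(2)
  w0 <- objective_weights("surface", nu = 0)
  Fa <- objective(stack, params3, ref, weights = w0)
  wpos <- objective_weights("surface", nu = 0.5)
  Fb <- objective(stack, params3, ref, weights = wpos)
  expect_equal(attr(Fa, "terms")$regularizer, attr(Fb, "terms")$regularizer)
  expect_equal(as.numeric(Fb - Fa), -0.5 * abs(log(4)), tolerance = 1e-10)
})

test_that("analytic gradient of F matches central finite differences", {
  stack <- tiny_stack()
  ref <- tiny_ref()
  cases <- list(list(mode = "surface", nsub = 1L),
                list(mode = "surface", nsub = 3L),  # slab integration
                list(mode = "atlas", nsub = 1L),
                list(mode = "atlas", nsub = 3L))
  for (cs in cases) {
    w <- objective_weights(cs$mode)
    par <- photorecon:::pack_params(init_params(stack, ref, cs$mode))
    par <- withr::with_seed(21, par + rnorm(length(par), sd = 0.05))
    res <- photorecon:::objective_core(stack, par, ref, w, cs$mode,
                                       grad = TRUE,
                                       slab_subsamples = cs$nsub)
    h <- 1e-5
    for (k in seq_along(par)) {
      e <- rep(0, length(par)); e[k] <- h
      fp <- photorecon:::objective_core(stack, par + e, ref, w, cs$mode,
                                        grad = FALSE,
                                        slab_subsamples = cs$nsub)$F
      fm <- photorecon:::objective_core(stack, par - e, ref, w, cs$mode,
                                        grad = FALSE,
                                        slab_subsamples = cs$nsub)$F
      fd <- (fp - fm) / (2 * h)
      expect_lt(abs(res$grad[k] - fd) / max(1e-8, abs(fd) + abs(res$grad[k])),
                1e-4)
    }
  }
})

test_that("F is invariant to a common rigid motion compensated by psi", {
  # rotate/translate every slice by the same rigid motion and give the
  # reference transform the compensating pose: F must not change. Smooth
  # soft-edged masks and images keep resampling errors second order.
  H <- 40; W <- 40; N <- 6
  g <- expand.grid(r = 1:H, c = 1:W)
  imgs <- array(0, c(H, W, N)); msks <- array(0, c(H, W, N))
  for (n in seq_len(N)) {
    rad <- sqrt((g$r - 20 - n / 3)^2 / 1.3 + (g$c - 21)^2 / 2)
    msks[, , n] <- matrix(pmin(pmax((12 - rad) / 4, 0), 1), H, W)
    imgs[, , n] <- msks[, , n] *
      matrix(0.5 + 0.3 * sin(g$r / 4 + n / 2) * cos(g$c / 5), H, W)
  }
  stack <- slice_stack(imgs, msks, pixel_size = 1, thickness = 2)
  refvol <- array(0, c(H, W, N))
  for (n in seq_len(N)) refvol[, , n] <- msks[, , n]
  ref <- reference_volume(refvol, c(1, 1, 2), "probabilistic_atlas")
  w <- objective_weights("surface", nu = 0)
  p0 <- init_params(stack, ref, "surface")
  hw <- c(H, W) + 20
  F0 <- objective(stack, p0, ref, weights = w, out_hw = hw)

  ang <- 0.12; tsh <- c(1.7, -2.3)
  p1 <- p0
  for (n in seq_along(p1$phi)) {
    th <- p1$phi[[n]]
    p1$phi[[n]] <- c(cos(ang) * th[1] - sin(ang) * th[2] + tsh[1],
                     sin(ang) * th[1] + cos(ang) * th[2] + tsh[2],
                     th[3] + ang, th[4:6])
  }
  # psi pulls stack coords to reference coords; composing the common
  # in-plane motion G into the slices means pulling through G^-1 first:
  # psi'(x) = psi(G^-1 x) = Rz(-ang) x - Rz(-ang) tsh + t0
  Rz <- matrix(c(cos(-ang), sin(-ang), 0, -sin(-ang), cos(-ang), 0, 0, 0, 1),
               3, 3)
  p1$psi <- c(as.vector(p0$psi[1:3] - Rz %*% c(tsh, 0)), 0, 0, -ang)
  F1 <- objective(stack, p1, ref, weights = w, out_hw = hw)
  expect_equal(as.numeric(F1), as.numeric(F0), tolerance = 2e-3)
})
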