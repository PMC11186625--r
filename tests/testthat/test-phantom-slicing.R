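# Phantom generation, digital slicing and the displacement error metric.

test_that("phantom generation is deterministic and paints all structures", {
  spec <- phantom_spec(seed = 7)
  a <- make_phantom(spec)
  b <- make_phantom(spec)
  expect_identical(a$labels, b$labels)
  expect_identical(a$intensity, b$intensity)
  expect_equal(sort(unique(as.vector(a$labels[a$labels > 0]))), 1:7)
  c2 <- make_phantom(phantom_spec(seed = 8))
  expect_false(identical(a$intensity, c2$intensity))
  # structures exceeding the grid are rejected
  bad <- list(list(label = 1, type = "ellipsoid", center = c(5, 5, 5),
                   semiaxes = c(30, 30, 30), value = 10))
  expect_error(phantom_spec(dims = c(20, 20, 20), structures = bad),
               "OverlapError")
})

test_that("jitterless undistorted slicing extracts exact planes", {
  ph <- small_phantom()
  cfg <- slicing_config(spacing = 4, jitter = 0, max_translation = 0,
                        max_rotation = 0, max_log_scale = 0, max_shear = 0,
                        illumination_amplitude = 0, min_foreground = 0,
                        seed = 2)
  sim <- digitally_slice(ph$intensity, ph$mask, cfg, voxel_size = 1)
  expect_equal(sim$stack$n, dim(ph$intensity)[3] %/% 4)  # floor(extent / S)
  for (n in c(1, 5, 10)) {
    expect_equal(sim$stack$images[, , n], ph$intensity[, , 1 + (n - 1) * 4],
                 tolerance = 1e-12)
  }
  expect_equal(sim$stack$thickness, 4)
})

test_that("slice counts follow floor(extent / spacing) on full coverage", {
  vol <- array(1, c(6, 6, 100))
  cfg <- slicing_config(spacing = 4, jitter = 0, max_translation = 0,
                        max_rotation = 0, max_log_scale = 0, max_shear = 0,
                        illumination_amplitude = 0, min_foreground = 0,
                        seed = 1)
  sim <- digitally_slice(vol, vol, cfg, voxel_size = 1)
  expect_equal(sim$stack$n, 25)
})

test_that("thickness jitter draws uniformly over the stated interval", {
  # j = 1, S = 4: the n-th cut is drawn from [n-1, n+1] in slice units,
  # i.e. offsets uniform over [-4, +4] voxels
  vol <- array(1, c(4, 4, 48))
  offs <- numeric(0)
  for (seed in 1:40) {
    cfg <- slicing_config(spacing = 4, jitter = 1, max_translation = 0,
                          max_rotation = 0, max_log_scale = 0, max_shear = 0,
                          illumination_amplitude = 0, min_foreground = 0,
                          seed = seed)
    sim <- digitally_slice(vol, vol, cfg, voxel_size = 1)
    zc <- (dim(vol)[3] + 1) / 2
    base <- 1 + (seq_len(length(sim$truth$z)) - 1) * 4 - zc
    offs <- c(offs, sim$truth$z - base)
  }
  # interior draws only (edge clipping truncates the first/last slices)
  offs <- offs[abs(offs) < 4 - 1e-9]
  expect_gt(length(offs), 300)
  h <- table(cut(offs, breaks = seq(-4, 4, by = 1)))
  p <- stats::chisq.test(h)$p.value
  expect_gt(p, 0.01)
  expect_lt(max(offs), 4 + 1e-9)
  expect_gt(min(offs), -4 - 1e-9)
})

test_that("stochastic slicing is reproducible bitwise under a fixed seed", {
  ph <- small_phantom()
  cfg <- slicing_config(spacing = 4, jitter = 0.2, seed = 11)
  s1 <- digitally_slice(ph$intensity, ph$mask, cfg, voxel_size = 1)
  s2 <- digitally_slice(ph$intensity, ph$mask, cfg, voxel_size = 1)
  expect_identical(s1$stack$images, s2$stack$images)
  expect_identical(s1$truth$z, s2$truth$z)
})

test_that("reconstruction_error matches a brute-force per-voxel loop", {
  ph <- small_phantom()
  cfg <- slicing_config(spacing = 8, jitter = 0, max_translation = 2,
                        max_rotation = 5, max_log_scale = 0.05,
                        max_shear = 0.05, illumination_amplitude = 0,
                        seed = 3)
  sim <- digitally_slice(ph$intensity, ph$mask, cfg, voxel_size = 1)
  N <- sim$stack$n
  # random recovered parameters near identity
  prm <- withr::with_seed(4, {
    structure(list(
      phi = lapply(seq_len(N), function(n)
        c(runif(2, -1, 1), runif(1, -0.05, 0.05), runif(2, -0.02, 0.02),
          runif(1, -0.02, 0.02))),
      s = 1.02, psi = c(runif(3, -1, 1), runif(3, -0.03, 0.03)),
      mode = "surface"), class = "recon_params")
  })
  res <- structure(list(params = prm), class = "recon_result")
  got <- reconstruction_error(res, sim, align = FALSE)

  # loop oracle
  g <- photorecon:::grid_mm(dim(sim$stack$masks)[1],
                            dim(sim$stack$masks)[2], 1)
  pm <- photorecon:::psi_matrix(prm$psi)
  zr <- photorecon:::slab_z(N, prm$s, sim$stack$thickness)
  tot <- 0; cnt <- 0
  for (n in seq_len(N)) {
    A <- phi_matrix(prm$phi[[n]])$A; b <- phi_matrix(prm$phi[[n]])$b
    tA <- sim$truth$phi[[n]]$A; tb <- sim$truth$phi[[n]]$b
    m <- sim$stack$masks[, , n]
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      if (m[i, j] <= 0.5) next
      u <- c(g$X[i, j], g$Y[i, j])
      rec <- pm$L %*% c(A %*% u + b, zr[n]) + pm$t
      tru <- c(tA %*% u + tb, sim$truth$z[n])
      tot <- tot + sqrt(sum((rec - tru)^2)); cnt <- cnt + 1
    }
  }
  expect_equal(got, tot / cnt, tolerance = 1e-9)

  # uniform 1 mm in-plane offset beyond truth, alignment disabled -> 1 mm
  prm2 <- structure(list(
    phi = lapply(seq_len(N), function(n) {
      tA <- sim$truth$phi[[n]]$A; tb <- sim$truth$phi[[n]]$b
      rot <- atan2(tA[2, 1], tA[1, 1])
      K <- solve(photorecon:::rot2(rot)) %*% tA
      c(tb[1] + 1, tb[2], rot, log(K[1, 1]), log(K[2, 2]), K[1, 2])
    }),
    s = 1, psi = c(0, 0, 0, 0, 0, 0), mode = "surface"),
    class = "recon_params")
  # psi translation must reproduce the truth z offsets on average; use the
  # exact per-slice z by matching the nominal grid to the truth
  ztru <- sim$truth$z
  znom <- photorecon:::slab_z(N, 1, sim$stack$thickness)
  prm2$psi[3] <- mean(ztru - znom)
  res2 <- structure(list(params = prm2), class = "recon_result")
  err2 <- reconstruction_error(res2, sim, align = FALSE)
  # z offsets are exact here only if jitter = 0 (uniform grid); offset is 1 mm in x
  expect_equal(err2, 1, tolerance = 1e-9)
  # recovered == truth -> 0
  prm3 <- prm2
  for (n in seq_len(N)) prm3$phi[[n]][1] <- prm3$phi[[n]][1] - 1
  res3 <- structure(list(params = prm3), class = "recon_result")
  expect_equal(reconstruction_error(res3, sim, align = FALSE), 0,
               tolerance = 1e-9)
  expect_equal(reconstruction_error(res3, sim, align = TRUE), 0,
               tolerance = 1e-7)
})
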