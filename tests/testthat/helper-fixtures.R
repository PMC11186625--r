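# Shared fixture builders. Everything is generated in code at test time.

# Small smooth random stack with rectangular-ish masks.
tiny_stack <- function(H = 8, W = 8, N = 4, seed = 1) {
  withr::with_seed(seed, {
    imgs <- array(runif(H * W * N, 0.25, 0.75), c(H, W, N))
    msks <- array(0, c(H, W, N))
    for (n in seq_len(N)) msks[3:(H - 2), 2:(W - 1), n] <- 1
    slice_stack(imgs, msks, pixel_size = 1, thickness = 2)
  })
}

# Random probabilistic reference volume.
tiny_ref <- function(dims = c(10, 10, 8), seed = 2, vox = 1.3) {
  withr::with_seed(seed,
    reference_volume(array(runif(prod(dims)), dims), vox,
                     "probabilistic_atlas"))
}

# Small phantom shared by the reconstruction tests.
small_phantom <- function(seed = 3) {
  make_phantom(phantom_spec(dims = c(48, 48, 64), seed = seed))
}

# High-contrast blob marker emulating a printed fiducial pattern.
blob_marker <- function(seed, size = 64) {
  withr::with_seed(seed, {
    m <- as.matrix(EBImage::gblur(matrix(runif(size^2), size, size), 3))
    m <- (m > stats::median(m)) * 1
    as.matrix(EBImage::gblur(m, 1))
  })
}

# Brute-force soft Dice (loop oracle).
dice_loop <- function(a, b, eps = 1e-6) {
  num <- 0; da <- 0; db <- 0
  av <- as.vector(a); bv <- as.vector(b)
  for (i in seq_along(av)) {
    num <- num + av[i] * bv[i]; da <- da + av[i]; db <- db + bv[i]
  }
  2 * num / (da + db + eps)
}

# Brute-force Pearson correlation over a support region (loop oracle).
ncc_loop <- function(a, b, w = NULL) {
  av <- as.vector(a); bv <- as.vector(b)
  if (!is.null(w)) {
    keep <- as.vector(w) > 0
    av <- av[keep]; bv <- bv[keep]
  }
  n <- length(av)
  ma <- sum(av) / n; mb <- sum(bv) / n
  num <- sum((av - ma) * (bv - mb))
  den <- sqrt(sum((av - ma)^2) * sum((bv - mb)^2))
  if (den == 0) 0 else num / den
}

# Brute-force AUROC by pair enumeration.
auroc_loop <- function(x, y) {
  tot <- 0
  for (yi in y) for (xi in x)
    tot <- tot + (yi > xi) + 0.5 * (yi == xi)
  tot / (length(x) * length(y))
}
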