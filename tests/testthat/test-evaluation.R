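# Evaluation statistics.

test_that("dice2d counts per-label overlaps and leaves absent labels NA", {
  a <- matrix(0L, 10, 10); a[2:4, 2:5] <- 1L; a[7:9, 7:9] <- 2L
  d <- dice2d(a, a)
  expect_equal(d$dice, c(1, 1))

  b <- matrix(0L, 10, 10); b[2:4, 7:9] <- 1L
  expect_equal(dice2d(a, b, labels = 1L)$dice, 0)

  # 10-px region vs the same region shifted so that 6 px overlap
  a2 <- matrix(0L, 6, 8); a2[2:3, 2:6] <- 1L  # 10 px
  b2 <- matrix(0L, 6, 8); b2[2:3, 4:8] <- 1L  # shifted, 6 px overlap? 2x3=6
  ov <- sum(a2 == 1 & b2 == 1)
  expect_equal(dice2d(a2, b2, labels = 1L)$dice, 2 * ov / 20)

  # label absent from both rasters: NA, not 0
  expect_true(is.na(dice2d(a, a, labels = 9L)$dice))
  expect_error(dice2d(a, matrix(0L, 3, 3)), "ShapeMismatch")
})

test_that("dice2d agrees with soft_dice on binarized rasters", {
  ph <- make_phantom(phantom_spec(dims = c(24, 24, 24), seed = 5))
  sl <- ph$labels[, , 12]
  sh <- ph$labels[, , 14]
  d1 <- dice2d(sl, sh, labels = 1L)$dice
  d2 <- soft_dice((sl == 1) * 1, (sh == 1) * 1)
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("label volumes scale with voxel size and match analytic shapes", {
  lab <- array(0L, c(12, 12, 12)); lab[2:11, 2:11, 2:11] <- 5L
  expect_equal(label_volumes(lab, 1)$volume_mm3, 1000)
  expect_equal(label_volumes(lab, 0.5)$volume_mm3, 125)

  # phantom ventricle against its analytic ellipsoid volume
  spec <- phantom_spec(dims = c(64, 64, 80), cut = NULL)
  ph <- make_phantom(spec)
  vd <- label_volumes(ph$labels, spec$voxel_size)
  st <- spec$structures[[3]]  # ventricle
  analytic <- 4 / 3 * pi * prod(st$semiaxes)
  got <- vd$volume_mm3[vd$label == 3]
  expect_lt(abs(got - analytic) / analytic, 0.03)
})

test_that("residualization removes exactly the age/sex fit", {
  tab <- withr::with_seed(21, tibble::tibble(
    case_id = 1:40, group = rep(0:1, 20),
    age = runif(40, 55, 90), sex = rep(c(0, 1), each = 20),
    hippocampus = rnorm(40, 3000, 300)))

  # volume exactly 2*age: residuals vanish
  t2 <- tab; t2$hippocampus <- 2 * t2$age
  r2 <- residualize(t2)
  expect_lt(max(abs(r2$hippocampus)), 1e-10)

  # orthogonal volume column: residuals are the centred values
  X <- cbind(1, tab$age, tab$sex)
  v <- withr::with_seed(22, rnorm(40))
  v_orth <- v - X %*% solve(crossprod(X), crossprod(X, v))
  t3 <- tab; t3$hippocampus <- as.vector(v_orth) + 10
  r3 <- residualize(t3)
  expect_equal(r3$hippocampus, as.vector(v_orth), tolerance = 1e-10)

  # random table against a hand-rolled normal-equations solve
  r1 <- residualize(tab)
  beta <- solve(crossprod(X), crossprod(X, tab$hippocampus))
  expect_equal(r1$hippocampus, as.vector(tab$hippocampus - X %*% beta),
               tolerance = 1e-8)
  expect_lt(abs(sum(r1$hippocampus * tab$age)) /
              sqrt(sum(r1$hippocampus^2) * sum(tab$age^2)), 1e-8)

  t4 <- tab; t4$sex <- 1  # constant covariate: rank deficient
  expect_error(residualize(t4), "RankDeficientDesign")
})

test_that("auroc equals normalized pair counts, with antisymmetry", {
  expect_equal(auroc(c(1, 2, 3), c(10, 11, 12)), 1)
  expect_equal(auroc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(auroc(c(1, 2, 3), c(2, 3, 4)), (1.5 + 2.5 + 3) / 9,
               tolerance = 1e-12)
  withr::with_seed(23, {
    for (i in 1:200) {
      x <- sample(1:8, sample(2:10, 1), replace = TRUE)
      y <- sample(1:8, sample(2:10, 1), replace = TRUE)
      expect_equal(auroc(x, y), auroc_loop(x, y), tolerance = 1e-12)
      expect_equal(auroc(x, y) + auroc(y, x), 1, tolerance = 1e-12)
    }
  })
  expect_error(auroc(numeric(0), 1:3), "EmptyGroup")
})

test_that("ranksum_p is exact for small samples and rank-invariant", {
  expect_equal(ranksum_p(c(1, 2), c(3, 4)), 2 / 6, tolerance = 1e-12)
  expect_equal(ranksum_p(c(5, 7, 9), c(5, 7, 9)), 1)
  # agreement with the normal approximation of the standard test for
  # larger samples
  x <- withr::with_seed(24, rnorm(30)); y <- withr::with_seed(25, rnorm(30) + 0.5)
  pw <- suppressWarnings(stats::wilcox.test(y, x, exact = FALSE,
                                            correct = TRUE)$p.value)
  expect_equal(ranksum_p(x, y), pw, tolerance = 1e-9)
  # invariance under common strictly monotone transforms
  expect_equal(ranksum_p(exp(x), exp(y)), ranksum_p(x, y), tolerance = 1e-12)
  expect_equal(ranksum_p(x^3, y^3), ranksum_p(x, y), tolerance = 1e-12)
})

test_that("pearson_r matches the direct formula and rejects degeneracies", {
  u <- c(1, 2, 3, 5); v <- c(2, 2, 4, 5)
  direct <- sum((u - mean(u)) * (v - mean(v))) /
    sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  expect_equal(pearson_r(u, v), direct, tolerance = 1e-12)
  expect_equal(pearson_r(u, u), 1)
  expect_equal(pearson_r(u, -2 * u + 7), -1)
  expect_error(pearson_r(u, rep(1, 4)), "ZeroVariance")
})

test_that("steiger_test matches an independent implementation", {
  # equal correlations: no evidence
  st <- steiger_test(0.8, 0.8, 0.5, 30)
  expect_equal(st$z, 0)
  expect_equal(st$p, 1)
  # antisymmetry under swapping the compared correlations
  a <- steiger_test(0.9, 0.7, 0.6, 24)
  b <- steiger_test(0.7, 0.9, 0.6, 24)
  expect_equal(a$z, -b$z, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)

  # second implementation of the published formula, coded independently
  steiger_oracle <- function(rjk, rjh, rkh, n) {
    fisher <- function(r) 0.5 * log((1 + r) / (1 - r))
    rbar <- mean(c(rjk, rjh))
    psi <- rkh * (1 - rbar^2 - rbar^2) -
      0.5 * (rbar * rbar) * (1 - rbar^2 - rbar^2 - rkh^2)
    cov <- psi / (1 - rbar^2)^2
    zstat <- (fisher(rjk) - fisher(rjh)) * sqrt((n - 3) / (2 - 2 * cov))
    list(z = zstat, p = 2 * (1 - pnorm(abs(zstat))))
  }
  for (case in list(c(0.9, 0.7, 0.6, 24), c(0.3, -0.2, 0.1, 50),
                    c(0.85, 0.8, 0.9, 33))) {
    got <- steiger_test(case[1], case[2], case[3], case[4])
    want <- steiger_oracle(case[1], case[2], case[3], case[4])
    expect_equal(got$z, want$z, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
  expect_error(steiger_test(1, 0.5, 0.2, 10), "InvalidCorrelation")
})

test_that("group_stats averages hemispheres and corrects confounds", {
  # synthetic cohort: hippocampal atrophy in cases, age confounded with
  # group; residualization must move the AUROC toward the confound-free
  # value
  n <- 60
  tab <- withr::with_seed(31, {
    group <- rep(0:1, each = n / 2)
    age <- 60 + group * 12 + rnorm(n, 0, 4)   # cases much older
    hip <- 3500 - 25 * (age - 60) - 150 * group + rnorm(n, 0, 80)
    tibble::tibble(case_id = seq_len(n), group = group, age = age,
                   sex = rep(c(0, 1), n / 2),
                   hippocampus_left = hip + rnorm(n, 0, 30),
                   hippocampus_right = hip + rnorm(n, 0, 30),
                   accumbens = rnorm(n, 500, 50))
  })
  res_raw <- group_stats(tab, correct_covariates = FALSE)
  res_adj <- group_stats(tab)
  expect_false("accumbens" %in% res_adj$region)   # excluded by default
  expect_true("hippocampus" %in% res_adj$region)  # averaged pair
  raw_auroc <- res_raw$auroc[res_raw$region == "hippocampus"]
  adj_auroc <- res_adj$auroc[res_adj$region == "hippocampus"]
  # confound-free effect: cases 150 units lower -> auroc clearly below 0.5;
  # the age confound exaggerates separation, correction moves it back up
  expect_lt(raw_auroc, adj_auroc)
  expect_lt(adj_auroc, 0.5)
  # bonferroni option appends adjusted p-values
  res_b <- group_stats(tab, bonferroni = TRUE)
  expect_true(all(res_b$p_bonferroni >= res_b$p_value))
})

test_that("method_correlations reports Steiger comparisons per region", {
  n <- 30
  dat <- withr::with_seed(33, {
    truth <- tibble::tibble(case_id = 1:n, hippocampus = rnorm(n, 3000, 300),
                            thalamus = rnorm(n, 6000, 500))
    a <- truth; a$hippocampus <- truth$hippocampus + rnorm(n, 0, 100)
    a$thalamus <- truth$thalamus + rnorm(n, 0, 200)
    b <- truth; b$hippocampus <- truth$hippocampus + rnorm(n, 0, 400)
    b$thalamus <- truth$thalamus + rnorm(n, 0, 800)
    list(truth = truth, a = a, b = b)
  })
  mc <- method_correlations(dat$truth, dat$a, dat$b)
  expect_equal(sort(mc$region), c("hippocampus", "thalamus"))
  expect_true(all(mc$r_a > mc$r_b))  # method A is less noisy by design
  expect_true(all(mc$steiger_p > 0 & mc$steiger_p <= 1))
})
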