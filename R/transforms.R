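# Planar and 3D transform parameterizations used by the registration.
#
# Planar transforms are parameterized so that the linear part always has a
# positive determinant during optimization:
#   affine: theta = (tx, ty, rot, ls1, ls2, sh)
#           A = R(rot) %*% [[exp(ls1), sh], [0, exp(ls2)]],  b = (tx, ty)
#   rigid:  theta = (tx, ty, rot), A = R(rot)
# The transform maps slice coordinates (mm, origin at the slice grid centre)
# to stack coordinates: u_stack = A %*% u_slice + b.
#
# The reference transform psi maps stack coordinates to reference
# coordinates (the pull direction used to resample the reference onto the
# stack grid):
#   rigid:  psi = (tx, ty, tz, rx, ry, rz), q = Rz(rz) Ry(ry) Rx(rx) x + t
#   affine: psi = (L11..L33 column-major, tx, ty, tz), q = L x + t

rot2 <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
drot2 <- function(a) matrix(c(-sin(a), cos(a), -cos(a), -sin(a)), 2, 2)

#' Planar transform matrix from parameters
#'
#' Builds the 2x2 linear part and translation of a per-slice planar
#' transform from its parameter vector.
#'
#' @param theta length-6 affine `(tx, ty, rot, ls1, ls2, sh)` or length-3
#'   rigid `(tx, ty, rot)` parameter vector; translations in mm, rotation in
#'   radians, `ls1`/`ls2` log-scales, `sh` shear.
#' @return list with `A` (2x2), `b` (length 2), and `theta`.
#' @export
phi_matrix <- function(theta) {
  if (length(theta) == 3) {
    A <- rot2(theta[3])
  } else if (length(theta) == 6) {
    K <- matrix(c(exp(theta[4]), 0, theta[6], exp(theta[5])), 2, 2)
    A <- rot2(theta[3]) %*% K
  } else stop("theta must have length 3 (rigid) or 6 (affine)")
  list(A = A, b = theta[1:2], theta = theta)
}

# Derivatives of A and b with respect to each parameter.
phi_matrix_grad <- function(theta) {
  n <- length(theta)
  R <- rot2(theta[3]); dR <- drot2(theta[3])
  dA <- vector("list", n); db <- vector("list", n)
  zero2 <- matrix(0, 2, 2)
  db[[1]] <- c(1, 0); db[[2]] <- c(0, 1)
  for (k in 3:n) db[[k]] <- c(0, 0)
  dA[[1]] <- zero2; dA[[2]] <- zero2
  if (n == 3) {
    dA[[3]] <- dR
  } else {
    K <- matrix(c(exp(theta[4]), 0, theta[6], exp(theta[5])), 2, 2)
    dA[[3]] <- dR %*% K
    dA[[4]] <- R %*% matrix(c(exp(theta[4]), 0, 0, 0), 2, 2)
    dA[[5]] <- R %*% matrix(c(0, 0, 0, exp(theta[5])), 2, 2)
    dA[[6]] <- R %*% matrix(c(0, 0, 1, 0), 2, 2)
  }
  list(dA = dA, db = db)
}

# Homogeneous 3x3 matrix for a planar transform parameter vector.
phi_homogeneous <- function(theta) {
  p <- phi_matrix(theta)
  rbind(cbind(p$A, p$b), c(0, 0, 1))
}

rot3x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot3y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot3z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
drot3x <- function(a) matrix(c(0, 0, 0, 0, -sin(a), cos(a), 0, -cos(a), -sin(a)), 3, 3)
drot3y <- function(a) matrix(c(-sin(a), 0, -cos(a), 0, 0, 0, cos(a), 0, -sin(a)), 3, 3)
drot3z <- function(a) matrix(c(-sin(a), cos(a), 0, -cos(a), -sin(a), 0, 0, 0, 0), 3, 3)

#' Reference transform matrix from parameters
#'
#' @param psi length-6 rigid `(tx, ty, tz, rx, ry, rz)` or length-12 affine
#'   (9 linear entries column-major followed by the translation).
#' @return list with `L` (3x3) and `t` (length 3).
#' @export
psi_matrix <- function(psi) {
  if (length(psi) == 6) {
    L <- rot3z(psi[6]) %*% rot3y(psi[5]) %*% rot3x(psi[4])
    list(L = L, t = psi[1:3])
  } else if (length(psi) == 12) {
    list(L = matrix(psi[1:9], 3, 3), t = psi[10:12])
  } else stop("psi must have length 6 (rigid) or 12 (affine)")
}

# dL/dparam for each psi parameter (translations give zero matrices).
psi_matrix_grad <- function(psi) {
  n <- length(psi)
  dL <- vector("list", n); dt <- vector("list", n)
  z3 <- matrix(0, 3, 3)
  if (n == 6) {
    Rx <- rot3x(psi[4]); Ry <- rot3y(psi[5]); Rz <- rot3z(psi[6])
    for (k in 1:3) { dL[[k]] <- z3; dt[[k]] <- as.numeric(1:3 == k) }
    dL[[4]] <- Rz %*% Ry %*% drot3x(psi[4]); dt[[4]] <- c(0, 0, 0)
    dL[[5]] <- Rz %*% drot3y(psi[5]) %*% Rx; dt[[5]] <- c(0, 0, 0)
    dL[[6]] <- drot3z(psi[6]) %*% Ry %*% Rx; dt[[6]] <- c(0, 0, 0)
  } else {
    for (k in 1:9) {
      E <- z3; E[(k - 1) %% 3 + 1, (k - 1) %/% 3 + 1] <- 1
      dL[[k]] <- E; dt[[k]] <- c(0, 0, 0)
    }
    for (k in 10:12) { dL[[k]] <- z3; dt[[k]] <- as.numeric(1:3 == (k - 9)) }
  }
  list(dL = dL, dt = dt)
}

#' Log-determinant regularizer of a planar affine transform
#'
#' Penalizes scaling and shear: the absolute value of the log of the
#' determinant of the 2x2 linear part of the transform's homogeneous 3x3
#' matrix. Zero exactly for area-preserving transforms (any rigid motion).
#'
#' @param phi a 3x3 homogeneous planar transform matrix, or a parameter
#'   vector accepted by [phi_matrix()].
#' @return non-negative scalar `|log det L|`.
#' @export
#' @examples
#' affine_penalty(diag(3))              # 0
#' affine_penalty(c(0, 0, 0, log(2), log(2), 0))  # |log 4|
affine_penalty <- function(phi) {
  L <- if (is.matrix(phi)) phi[1:2, 1:2] else phi_matrix(phi)$A
  d <- L[1, 1] * L[2, 2] - L[1, 2] * L[2, 1]
  if (d <= 0) stop("SingularTransform: linear part has non-positive determinant")
  abs(log(d))
}

# Fit a 3x3 projective homography mapping points `src` (n x 2) to `dst`
# (n x 2) by the normalized DLT. Needs n >= 4, no 3 src points collinear.
fit_homography <- function(src, dst) {
  stopifnot(nrow(src) == nrow(dst), nrow(src) >= 4)
  norm_pts <- function(p) {
    c0 <- colMeans(p)
    sc <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, c0)^2)))
    T <- matrix(c(sc, 0, 0, 0, sc, 0, -sc * c0[1], -sc * c0[2], 1), 3, 3)
    list(T = T, p = sweep(p, 2, c0) * sc)
  }
  ns <- norm_pts(src); nd <- norm_pts(dst)
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- ns$p[i, 1]; y <- ns$p[i, 2]
    u <- nd$p[i, 1]; v <- nd$p[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ]     <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  # null vector of A: eigenvector of A'A with the smallest eigenvalue
  h <- eigen(crossprod(A), symmetric = TRUE)$vectors[, 9]
  H <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% H %*% ns$T
  H / H[3, 3]
}

# Apply a 3x3 homography to n x 2 points.
apply_homography <- function(H, pts) {
  p <- cbind(pts, 1) %*% t(H)
  p[, 1:2, drop = FALSE] / p[, 3]
}

# Least-squares similarity transform (scale, rotation, translation) mapping
# src to dst (both n x 2), by Procrustes / Umeyama closed form.
fit_similarity <- function(src, dst) {
  ms <- colMeans(src); md <- colMeans(dst)
  S <- sweep(src, 2, ms); D <- sweep(dst, 2, md)
  C <- t(D) %*% S / nrow(src)
  sv <- svd(C)
  sgn <- diag(c(1, sign(det(sv$u %*% t(sv$v)))))
  R <- sv$u %*% sgn %*% t(sv$v)
  varS <- mean(rowSums(S^2))
  sc <- sum(diag(sgn) * sv$d) / varS
  t <- md - sc * as.vector(R %*% ms)
  list(scale = sc, R = R, t = t,
       apply = function(p) sweep(p %*% t(sc * R), 2, t, `+`))
}
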