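#' @useDynLib moldock, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

## Small geometry helpers shared by the pose decoder, restraints and fixtures.
## Angles are degrees at every user-facing surface; radians internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Normalise angles to the interval (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector with every element in (-180, 180].
#' @export
normalizeAngle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

## Elementary rotation matrices (angles in radians).
rotX <- function(t) {
  c <- cos(t); s <- sin(t)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rotY <- function(t) {
  c <- cos(t); s <- sin(t)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rotZ <- function(t) {
  c <- cos(t); s <- sin(t)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Rotation matrix from Euler angles (heading, attitude, bank)
#'
#' Tait-Bryan z-y'-x'' intrinsic convention: heading rotates about the lab z
#' axis, attitude about the resulting y axis, bank about the resulting x axis.
#' The matrix maps lab-frame axes onto the rotated frame, i.e.
#' \code{E = Rz(heading) Ry(attitude) Rx(bank)}.
#'
#' @param heading,attitude,bank angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
eulerMatrix <- function(heading, attitude, bank) {
  rotZ(deg2rad(heading)) %*% rotY(deg2rad(attitude)) %*% rotX(deg2rad(bank))
}

#' Euler angles (heading, attitude, bank) of a rotation matrix
#'
#' Inverse of [eulerMatrix()]. At the gimbal singularity (attitude = +/-90
#' degrees) bank is set to 0 and heading absorbs the free angle.
#'
#' @param R 3x3 rotation matrix.
#' @return named numeric vector (heading, attitude, bank) in degrees.
#' @export
matrixToEuler <- function(R) {
  sa <- -R[3, 1]
  sa <- min(1, max(-1, sa))
  attitude <- asin(sa)
  if (abs(sa) < 1 - 1e-10) {
    heading <- atan2(R[2, 1], R[1, 1])
    bank <- atan2(R[3, 2], R[3, 3])
  } else {
    heading <- atan2(-R[1, 2], R[2, 2])
    bank <- 0
  }
  c(heading = rad2deg(heading), attitude = rad2deg(attitude),
    bank = rad2deg(bank))
}

#' Principal axes of a coordinate set
#'
#' Eigenvectors of the gyration tensor about the centroid, ordered by
#' decreasing principal moment (longest axis first). Signs are fixed
#' deterministically: each of the first two axes is flipped so that the atom
#' with the largest absolute projection has a positive projection (ties broken
#' by lowest atom index); the third axis is their cross product, making the
#' frame right-handed.
#'
#' @param X n x 3 coordinate matrix.
#' @return list with \code{axes} (3x3 matrix, rows = axis vectors) and
#'   \code{center} (centroid).
#' @export
principalAxes <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  S <- crossprod(Xc) / nrow(Xc)
  e <- eigen(S, symmetric = TRUE)
  A <- t(e$vectors)  # rows = axes, ordered by decreasing eigenvalue
  for (k in 1:2) {
    pr <- Xc %*% A[k, ]
    i <- which.max(abs(pr))
    if (length(i) && abs(pr[i]) > 1e-12 && pr[i] < 0) A[k, ] <- -A[k, ]
  }
  A[3, ] <- c(A[1, 2] * A[2, 3] - A[1, 3] * A[2, 2],
              A[1, 3] * A[2, 1] - A[1, 1] * A[2, 3],
              A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1])
  list(axes = A, center = ctr)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation minimising
#' \code{sum |R (X - cX) + cY - Y|^2}, i.e. superposes \code{X} onto \code{Y}.
#'
#' @param X,Y n x 3 coordinate matrices in 1:1 correspondence.
#' @return list with \code{R} (3x3 proper rotation), \code{centerX},
#'   \code{centerY} and \code{rmsd} of the superposed match.
#' @export
kabsch <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), ncol(X) == 3, ncol(Y) == 3)
  cX <- colMeans(X); cY <- colMeans(Y)
  Xc <- sweep(X, 2, cX); Yc <- sweep(Y, 2, cY)
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Xr <- Xc %*% t(R)
  list(R = R, centerX = cX, centerY = cY,
       rmsd = sqrt(mean(rowSums((Xr - Yc)^2))))
}

#' Rotation angle of a rotation matrix
#'
#' @param R 3x3 rotation matrix.
#' @return angle in degrees in [0, 180].
#' @export
rotationAngle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  rad2deg(acos(min(1, max(-1, ct))))
}

## Rodrigues rotation about a unit axis through the origin.
axisAngleMatrix <- function(axis, angleDeg) {
  a <- axis / sqrt(sum(axis^2))
  t <- deg2rad(angleDeg)
  c <- cos(t); s <- sin(t); C <- 1 - c
  matrix(c(
    c + a[1]^2 * C,        a[2] * a[1] * C + a[3] * s, a[3] * a[1] * C - a[2] * s,
    a[1] * a[2] * C - a[3] * s, c + a[2]^2 * C,        a[3] * a[2] * C + a[1] * s,
    a[1] * a[3] * C + a[2] * s, a[2] * a[3] * C - a[1] * s, c + a[3]^2 * C
  ), 3, 3)
}

## Dihedral angle a-b-c-d in degrees, IUPAC sign convention.
dihedralAngleXYZ <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  nb2 <- sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / nb2
  rad2deg(atan2(y, x))
}
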