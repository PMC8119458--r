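#' Rigid-body transforms and basic vector geometry
#'
#' Internal helpers shared by every module: 3-vectors are numeric length-3,
#' coordinate sets are N x 3 matrices, rotations are 3 x 3 orthonormal
#' matrices with determinant +1.
#'
#' @name transforms
#' @keywords internal
NULL

DEGENERATE_TOL <- 1e-6

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < DEGENERATE_TOL) {
    stop("degenerate geometry: vector norm below ", DEGENERATE_TOL, " A")
  }
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle in degrees to [-180, 180)
#' @keywords internal
wrap180 <- function(x) ((x + 180) %% 360) - 180

#' Rotation matrix about an arbitrary unit axis (Rodrigues)
#' @param axis unit 3-vector
#' @param angle rotation angle in radians
#' @keywords internal
rot_axis <- function(axis, angle) {
  u <- axis / vnorm(axis)
  K <- matrix(c(0, u[3L], -u[2L],
                -u[3L], 0, u[1L],
                u[2L], -u[1L], 0), 3L, 3L)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Minimal rotation carrying unit vector a onto unit vector b
#' @keywords internal
rotation_between <- function(a, b) {
  a <- a / vnorm(a)
  b <- b / vnorm(b)
  d <- sum(a * b)
  if (d > 1 - 1e-12) return(diag(3L))
  if (d < -1 + 1e-12) {
    # 180 degrees about any axis perpendicular to a
    p <- cross3(a, c(1, 0, 0))
    if (vnorm(p) < 1e-6) p <- cross3(a, c(0, 1, 0))
    return(rot_axis(p, pi))
  }
  rot_axis(cross3(a, b), acos(max(-1, min(1, d))))
}

#' Create a rigid transform
#'
#' A rigid transform maps points by `R %*% x + t`.  Equivalent to the
#' 3 x 4 matrices used on fold-tree edges.
#'
#' @param R 3 x 3 rotation matrix (det +1)
#' @param t translation 3-vector
#' @return an object of class `rigid_transform`
#' @export
rigid_transform <- function(R = diag(3L), t = c(0, 0, 0)) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)), length(t) == 3L)
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

#' Compose two rigid transforms (apply `b` first, then `a`)
#' @param a,b rigid transforms
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param a a rigid transform
#' @export
rt_invert <- function(a) {
  Rt <- t(a$R)
  rigid_transform(Rt, as.numeric(-Rt %*% a$t))
}

#' Apply a rigid transform to points
#' @param a a rigid transform
#' @param x a 3-vector or an N x 3 matrix of coordinates
#' @export
rt_apply <- function(a, x) {
  if (is.matrix(x)) {
    sweep(x %*% t(a$R), 2L, a$t, "+")
  } else {
    as.numeric(a$R %*% x) + a$t
  }
}

#' Bond angle a-b-c in degrees
#' @keywords internal
bond_angle <- function(a, b, c) {
  u <- unit(a - b)
  v <- unit(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Dihedral angle a-b-c-d in degrees, wrapped to [-180, 180)
#' @keywords internal
dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / vnorm(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap180(rad2deg(atan2(y, x)))
}

#' Place an atom from internal coordinates (natural extension)
#'
#' Given a bonded chain a-b-c, returns the position of d bonded to c with
#' the stated bond length, bond angle b-c-d and torsion a-b-c-d.
#'
#' @param a,b,c 3-vectors of the three reference atoms
#' @param bond length c-d in Angstrom
#' @param angle bond angle b-c-d in degrees
#' @param torsion dihedral a-b-c-d in degrees (scalar or vector)
#' @return a 3-vector, or an N x 3 matrix when `torsion` has length N
#' @keywords internal
nerf_place <- function(a, b, c, bond, angle, torsion) {
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  M <- cbind(bc, cross3(n, bc), n)
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  d2 <- cbind(-bond * cos(ang),
              bond * sin(ang) * cos(tor),
              -bond * sin(ang) * sin(tor))
  out <- sweep(d2 %*% t(M), 2L, c, "+")
  if (length(torsion) == 1L) as.numeric(out) else out
}

#' Optimal-superposition RMSD between two point sets
#'
#' Least-squares root-mean-square deviation after optimal rigid
#' superposition (Kabsch algorithm, with the usual reflection guard).
#'
#' @param coordsA,coordsB N x 3 coordinate matrices, equal N >= 3
#' @return RMSD in Angstrom
#' @export
superpose_rmsd <- function(coordsA, coordsB) {
  coordsA <- as.matrix(coordsA)
  coordsB <- as.matrix(coordsB)
  if (!all(dim(coordsA) == dim(coordsB))) {
    stop("superpose_rmsd: coordinate sets differ in size")
  }
  if (nrow(coordsA) < 3L) stop("superpose_rmsd: need at least 3 points")
  ca <- colMeans(coordsA)
  cb <- colMeans(coordsB)
  A <- sweep(coordsA, 2L, ca)
  B <- sweep(coordsB, 2L, cb)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  diff <- B - A %*% t(R)
  sqrt(sum(diff * diff) / nrow(A))
}

#' Kabsch rotation + translation superposing A onto B
#' @keywords internal
superpose_fit <- function(coordsA, coordsB) {
  ca <- colMeans(coordsA)
  cb <- colMeans(coordsB)
  A <- sweep(coordsA, 2L, ca)
  B <- sweep(coordsB, 2L, cb)
  sv <- svd(t(A) %*% B)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, as.numeric(cb - R %*% ca))
}
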