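#' Nucleobase reference frames and the pseudo-atom orientation metric
#'
#' Each base is treated as a rigid body carrying a local right-handed
#' coordinate system with origin at C1'.  For purines (A, G) the x-axis
#' points along C1'->N9 and the z-axis along C1'N9 x N9C4; for
#' pyrimidines (U, C) the x-axis points along C1'->N1 and the z-axis
#' along C1'N1 x N1C2.  The relative placement of two bases is described
#' by six degrees of freedom: the origin-origin distance r, the twist
#' omega about the inter-origin axis, and the inter-origin direction
#' expressed in each local frame.
#'
#' @name base-frames
NULL

#' Frame-defining atoms per base type
#' @keywords internal
FRAME_ATOMS <- list(
  A = c("N9", "C4"),
  G = c("N9", "C4"),
  U = c("N1", "C2"),
  C = c("N1", "C2")
)

#' Pseudo-atom template shared by all base types
#'
#' Four fixed points in the base-local coordinate system that represent a
#' base's orientation for the distance-matrix metric.  The same four
#' points are used for all four base types.
#'
#' @return a 4 x 3 matrix (rows T1..T4, Angstrom, base-local coordinates)
#' @export
pseudo_atom_template <- function() {
  m <- rbind(
    T1 = c(2.158, 3.826, 1.427),
    T2 = c(-0.789, -0.329, -1.273),
    T3 = c(4.520, -3.006, 1.586),
    T4 = c(6.018, 1.903, -1.638)
  )
  colnames(m) <- c("x", "y", "z")
  m
}

is_purine <- function(type) type %in% c("A", "G")

#' Construct a base residue record
#'
#' @param chain chain identifier (single character)
#' @param resno residue index (integer)
#' @param type base type, one of "A", "C", "G", "U"
#' @param xyz named N x 3 matrix of heavy-atom coordinates (PDB names)
#' @return an object of class `base_residue`
#' @export
base_residue <- function(chain, resno, type, xyz) {
  type <- as.character(type)
  if (!type %in% c("A", "C", "G", "U")) {
    stop("unsupported base type '", type, "': only standard A, C, G, U")
  }
  xyz <- as.matrix(xyz)
  if (is.null(rownames(xyz))) stop("atom table must have atom-name rownames")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in residue ", resno)
  structure(list(chain = as.character(chain), resno = as.integer(resno),
                 type = type, xyz = xyz),
            class = "base_residue")
}

#' Build the local coordinate system of a nucleobase
#'
#' Origin at C1'; x along C1'->N9 (purines) or C1'->N1 (pyrimidines);
#' z along the cross product of the glycosidic bond with the first
#' in-ring bond (N9->C4 or N1->C2); y completes the right-handed set.
#'
#' @param residue a `base_residue`
#' @return an object of class `base_frame` with fields `origin` and
#'   `axes` (3 x 3 matrix whose columns are the x, y, z axes)
#' @export
build_base_frame <- function(residue) {
  atoms <- FRAME_ATOMS[[residue$type]]
  need <- c("C1'", atoms)
  for (a in need) {
    if (!a %in% rownames(residue$xyz)) {
      stop("cannot build base frame: missing atom ", a,
           " in residue ", residue$resno)
    }
  }
  o <- residue$xyz["C1'", ]
  n <- residue$xyz[atoms[1L], ]
  c2 <- residue$xyz[atoms[2L], ]
  v1 <- n - o
  v2 <- c2 - n
  if (vnorm(cross3(v1, v2)) < DEGENERATE_TOL) {
    stop("degenerate geometry: frame atoms of residue ", residue$resno,
         " are collinear")
  }
  x <- unit(v1)
  z <- unit(cross3(v1, v2))
  y <- cross3(z, x)
  base_frame(o, cbind(x, y, z))
}

#' Create a base frame from an origin and axes
#' @param origin 3-vector (C1' position)
#' @param axes 3 x 3 orthonormal matrix, columns x, y, z, det +1
#' @export
base_frame <- function(origin, axes) {
  stopifnot(length(origin) == 3L, all(dim(axes) == c(3L, 3L)))
  err <- max(abs(t(axes) %*% axes - diag(3L)))
  if (err > 1e-6 || det(axes) < 0) {
    stop("base_frame: axes not right-handed orthonormal (error ", err, ")")
  }
  if (err > 1e-12) {
    # snap accumulated round-off back onto SO(3) (polar decomposition)
    sv <- svd(axes)
    axes <- sv$u %*% t(sv$v)
  }
  structure(list(origin = as.numeric(origin), axes = axes),
            class = "base_frame")
}

#' Transform a base frame by a rigid motion
#' @keywords internal
frame_transform <- function(frame, rt) {
  base_frame(rt_apply(rt, frame$origin), rt$R %*% frame$axes)
}

#' Frame-to-frame rigid transform (parent-local coordinates)
#'
#' Returns the transform that expresses frame `b` relative to frame `a`,
#' i.e. the 3 x 4 edge matrix such that composing `a` with it recovers
#' `b` in global coordinates.
#' @keywords internal
frame_relative_rt <- function(a, b) {
  rigid_transform(t(a$axes) %*% b$axes,
                  as.numeric(t(a$axes) %*% (b$origin - a$origin)))
}

frame_from_relative_rt <- function(a, rt) {
  base_frame(as.numeric(a$axes %*% rt$t) + a$origin, a$axes %*% rt$R)
}

#' Relative orientation between two base frames
#'
#' Six-dimensional relative placement: the origin-origin distance `r`,
#' the inter-origin direction in each frame's local coordinates
#' (`dir_ij`, `dir_ji`) and the twist `omega` about the inter-origin
#' axis.  Omega is the signed angle (right-hand rule about the i->j
#' axis) from the projection of frame i's x-axis onto the plane normal
#' to that axis to the projection of frame j's x-axis.  Note this twist
#' is invariant under exchanging i and j (like any dihedral angle);
#' exchanging the arguments swaps `dir_ij` and `dir_ji` and keeps `r`
#' and `omega`.
#'
#' @param frame_i,frame_j `base_frame` objects with distinct origins
#' @return an object of class `relative_orientation` with fields
#'   `r` (Angstrom), `omega` (degrees in [-180, 180)), `dir_ij`,
#'   `dir_ji` (unit 3-vectors in local coordinates)
#' @export
relative_orientation <- function(frame_i, frame_j) {
  v <- frame_j$origin - frame_i$origin
  r <- vnorm(v)
  if (r < DEGENERATE_TOL) stop("degenerate geometry: coincident origins")
  u <- v / r
  dir_ij <- as.numeric(t(frame_i$axes) %*% u)
  dir_ji <- as.numeric(t(frame_j$axes) %*% (-u))
  xi <- frame_i$axes[, 1L]
  xj <- frame_j$axes[, 1L]
  pi_ <- xi - sum(xi * u) * u
  pj_ <- xj - sum(xj * u) * u
  omega <- wrap180(rad2deg(atan2(sum(cross3(pi_, pj_) * u), sum(pi_ * pj_))))
  structure(list(r = r, omega = omega, dir_ij = dir_ij, dir_ji = dir_ji),
            class = "relative_orientation")
}

#' Reconstruct frame j from frame i and a relative orientation
#'
#' Exact inverse of [relative_orientation()]: the six parameters fix the
#' second frame completely.
#'
#' @param frame_i a `base_frame`
#' @param orient a `relative_orientation`
#' @return the reconstructed `base_frame` of residue j
#' @export
frame_from_orientation <- function(frame_i, orient) {
  u <- as.numeric(frame_i$axes %*% orient$dir_ij)
  u <- u / vnorm(u)
  oj <- frame_i$origin + orient$r * u
  # any rotation A0 with A0 %*% dir_ji = -u, then twist about u to set omega
  A0 <- rotation_between(orient$dir_ji, -u)
  f0 <- base_frame(oj, A0)
  w0 <- relative_orientation(frame_i, f0)$omega
  phi <- deg2rad(wrap180(orient$omega - w0))
  base_frame(oj, rot_axis(u, phi) %*% A0)
}

#' Pseudo-atom positions of a base in global coordinates
#' @param frame a `base_frame`
#' @return 4 x 3 matrix
#' @keywords internal
pseudo_atoms <- function(frame) {
  sweep(pseudo_atom_template() %*% t(frame$axes), 2L, frame$origin, "+")
}

#' Pair configuration: the 4 x 4 pseudo-atom cross-distance matrix
#'
#' The relative placement of two bases is summarized by the 16 distances
#' between the four pseudo-atoms of base i and the four pseudo-atoms of
#' base j.  This representation is invariant to global rigid motion of
#' the pair.
#'
#' @param frame_i,frame_j base frames
#' @param types character 2-vector of base types, e.g. c("G", "C")
#' @param sep separation class, one of "1", "2", "2+"
#' @return an object of class `pair_configuration` with the distance
#'   matrix in `D` (and flattened in `d16`)
#' @export
pair_configuration <- function(frame_i, frame_j, types = c("N", "N"),
                               sep = "2+") {
  Pi <- pseudo_atoms(frame_i)
  Pj <- pseudo_atoms(frame_j)
  D <- cross_dist(Pi, Pj)
  structure(list(types = types, sep = sep, D = D, d16 = as.numeric(D)),
            class = "pair_configuration")
}

#' All pairwise distances between two coordinate sets
#' @keywords internal
cross_dist <- function(A, B) {
  m <- nrow(A); k <- nrow(B)
  d2 <- A %*% t(B)
  d2 <- rowSums(A * A) - 2 * d2
  d2 <- d2 + rep(rowSums(B * B), each = m)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Distance-matrix deviation between two pair configurations
#'
#' Root-mean-square of the 16 element-wise differences between the two
#' configurations' pseudo-atom cross-distance matrices.  A rotation- and
#' translation-invariant pseudo-metric that closely tracks superposition
#' RMSD while being far cheaper: zero for congruent configurations,
#' symmetric, non-negative.
#'
#' @param configA,configB `pair_configuration` objects of the same base
#'   types
#' @return deviation in Angstrom
#' @export
ddm <- function(configA, configB) {
  if (!identical(configA$types, configB$types)) {
    stop("ddm: configurations have different base types (",
         paste(configA$types, collapse = ""), " vs ",
         paste(configB$types, collapse = ""), ")")
  }
  ddm_vec(configA$d16, configB$d16)
}

#' DDM on flattened 16-distance vectors (no type check)
#' @keywords internal
ddm_vec <- function(a, b) sqrt(mean((a - b)^2))

#' DDM from one configuration to each row of a 16-column matrix
#' @keywords internal
ddm_to_all <- function(d16, M) {
  if (is.null(dim(M)) || nrow(M) == 0L) return(numeric(0L))
  sqrt(rowMeans(sweep(M, 2L, d16)^2))
}
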