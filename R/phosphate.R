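#' Phosphate placement between consecutive riboses
#'
#' The phosphate group (P, OP1, OP2, O5') bridging residue i's O3' and
#' residue i+1's C5' is fully determined by the two torsions epsilon
#' (C2'i-C3'i-O3'i-P) and zeta (C3'i-O3'i-P-O5') given fixed bond
#' lengths and angles on the 5' side.  The O5'-C5' bond and its two
#' flanking angles are deliberately flexible: their strain, plus the
#' backbone torsion statistics, defines the internal energy minimized
#' when a connection is rebuilt.
#'
#' @name phosphate
NULL

# fixed phosphate internal geometry (crystallographic means)
P_GEOM <- list(
  o3_p = 1.607, ang_c3_o3_p = 119.7,
  p_o5 = 1.593, ang_o3_p_o5 = 104.0,
  p_op = 1.485, ang_o3_p_op = 107.7, op_twist = 119
)

# flexible closure targets
CLOSE_GEOM <- list(
  bl = 1.422, k_bond = 5.0,
  th_poc = 120.7, th_occ = 111.1, k_angle = 0.1
)

rows_norm <- function(M) sqrt(rowSums(M * M))

rows_cross <- function(A, B) {
  cbind(A[, 2L] * B[, 3L] - A[, 3L] * B[, 2L],
        A[, 3L] * B[, 1L] - A[, 1L] * B[, 3L],
        A[, 1L] * B[, 2L] - A[, 2L] * B[, 1L])
}

# vectorized dihedral over rows; arguments are N x 3 matrices
dihedral_rows <- function(A, B, C, D) {
  b1 <- B - A; b2 <- C - B; b3 <- D - C
  n1 <- rows_cross(b1, b2)
  n2 <- rows_cross(b2, b3)
  m1 <- rows_cross(n1, b2 / rows_norm(b2))
  wrap180(rad2deg(atan2(rowSums(m1 * n2), rowSums(n1 * n2))))
}

as_rows <- function(x, n) {
  if (is.matrix(x)) x else matrix(x, n, 3L, byrow = TRUE)
}

# natural-extension placement where the reference atoms may vary per row
nerf_rows <- function(A, B, C, bond, angle, torsion) {
  n <- max(nrow(as.matrix(A)), length(torsion),
           if (is.matrix(C)) nrow(C) else 1L)
  A <- as_rows(A, n); B <- as_rows(B, n); C <- as_rows(C, n)
  bc <- C - B
  bc <- bc / rows_norm(bc)
  nv <- rows_cross(B - A, bc)
  nv <- nv / rows_norm(nv)
  mv <- rows_cross(nv, bc)
  ang <- deg2rad(angle); tor <- deg2rad(torsion)
  C + (-bond * cos(ang)) * bc +
    (bond * sin(ang) * cos(tor)) * mv +
    (-bond * sin(ang) * sin(tor)) * nv
}

#' Phosphate atom coordinates from epsilon/zeta torsions
#'
#' @param rib_i named coordinate matrix of residue i containing C2',
#'   C3', O3'
#' @param eps,zeta torsion vectors in degrees (equal length)
#' @return list of matrices `P` and `O5` (one row per torsion pair)
#' @keywords internal
place_phosphate <- function(rib_i, eps, zeta) {
  n <- length(eps)
  P <- nerf_rows(rib_i["C2'", ], rib_i["C3'", ], rib_i["O3'", ],
                 P_GEOM$o3_p, P_GEOM$ang_c3_o3_p, eps)
  O5 <- nerf_rows(as_rows(rib_i["C3'", ], n), as_rows(rib_i["O3'", ], n),
                  P, P_GEOM$p_o5, P_GEOM$ang_o3_p_o5, zeta)
  list(P = P, O5 = O5)
}

#' Internal (bond + angle + torsion) energy of a phosphate closure
#'
#' Vectorized over candidate placements.  The torsion contribution uses
#' the three conditional backbone-torsion tables when supplied.
#'
#' @keywords internal
closure_internal_energy <- function(rib_i, rib_j, P, O5, eps, zeta,
                                    tables = NULL) {
  n <- nrow(P)
  C5 <- as_rows(rib_j["C5'", ], n)
  C4 <- as_rows(rib_j["C4'", ], n)
  O4j <- as_rows(rib_j["O4'", ], n)
  bl <- rows_norm(O5 - C5)
  # angles P-O5'-C5' and O5'-C5'-C4'
  u1 <- (P - O5) / rows_norm(P - O5)
  v1 <- (C5 - O5) / rows_norm(C5 - O5)
  th1 <- rad2deg(acos(pmax(-1, pmin(1, rowSums(u1 * v1)))))
  u2 <- (O5 - C5) / rows_norm(O5 - C5)
  v2 <- (C4 - C5) / rows_norm(C4 - C5)
  th2 <- rad2deg(acos(pmax(-1, pmin(1, rowSums(u2 * v2)))))
  e <- softened_harmonic(CLOSE_GEOM$k_bond * (bl - CLOSE_GEOM$bl)) +
    softened_harmonic(CLOSE_GEOM$k_angle * (th1 - CLOSE_GEOM$th_poc)) +
    softened_harmonic(CLOSE_GEOM$k_angle * (th2 - CLOSE_GEOM$th_occ))
  if (!is.null(tables)) {
    O3 <- as_rows(rib_i["O3'", ], n)
    alpha <- dihedral_rows(O3, P, O5, C5)
    beta <- dihedral_rows(P, O5, C5, C4)
    gamma <- dihedral_rows(O5, C5, C4, O4j)
    nui <- pucker_nu(rib_i)
    nuj <- pucker_nu(rib_j)
    e <- e + etorsion_terms(nui, eps, zeta, alpha, beta, gamma, nuj, tables)
  }
  e
}

# deterministic quasi-uniform representatives on the eps-zeta torus
PHOS_REPS <- local({
  k <- 0:49
  golden <- (sqrt(5) - 1) / 2
  cbind(eps = -180 + 360 * (k + 0.5) / 50,
        zeta = ((k * golden * 360 + 180) %% 360) - 180)
})

#' Rebuild the phosphate between two consecutive riboses
#'
#' Hierarchical grid search over the epsilon-zeta torus: 50 coarse
#' representatives, 50 sub-representatives around the best coarse point,
#' then a 5 x 5 local grid in 1 degree steps -- 125 internal-energy
#' evaluations in total.  Returns the lowest-energy placement of P, OP1,
#' OP2 and O5'.
#'
#' @param rib_i,rib_j coordinate matrices of residues i and i+1 (each
#'   containing the sugar atoms; `rib_j` must have C5', C4', O4')
#' @param tables optional backbone-torsion tables (see
#'   [collect_torsion_stats()])
#' @return list with fields `eps`, `zeta`, `xyz` (4 x 3 matrix of P,
#'   OP1, OP2, O5'), `energy`, `n_eval` and `failed` (TRUE when no
#'   candidate closes the backbone within reach)
#' @export
rebuild_phosphate <- function(rib_i, rib_j, tables = NULL) {
  eval_batch <- function(eps, zeta) {
    pl <- place_phosphate(rib_i, eps, zeta)
    e <- closure_internal_energy(rib_i, rib_j, pl$P, pl$O5, eps, zeta,
                                 tables)
    list(e = e, pl = pl)
  }
  n_eval <- 0L
  # level 1: coarse representatives
  b1 <- eval_batch(PHOS_REPS[, 1L], PHOS_REPS[, 2L])
  n_eval <- n_eval + nrow(PHOS_REPS)
  i1 <- which.min(b1$e)
  c1 <- PHOS_REPS[i1, ]
  # level 2: 50 sub-representatives within the coarse cell
  k <- 0:49
  golden <- (sqrt(5) - 1) / 2
  de <- -25 + 50 * (k + 0.5) / 50
  dz <- ((k * golden * 50 + 25) %% 50) - 25
  e2 <- wrap180(c1[1L] + de)
  z2 <- wrap180(c1[2L] + dz)
  b2 <- eval_batch(e2, z2)
  n_eval <- n_eval + length(e2)
  i2 <- which.min(b2$e)
  # level 3: 5 x 5 grid in 1 degree steps
  g <- expand.grid(de = -2:2, dz = -2:2)
  e3 <- wrap180(e2[i2] + g$de)
  z3 <- wrap180(z2[i2] + g$dz)
  b3 <- eval_batch(e3, z3)
  n_eval <- n_eval + length(e3)
  i3 <- which.min(b3$e)
  eps <- e3[i3]; zeta <- z3[i3]
  P <- b3$pl$P[i3, ]; O5 <- b3$pl$O5[i3, ]
  op1 <- nerf_place(rib_i["C3'", ], rib_i["O3'", ], P, P_GEOM$p_op,
                    P_GEOM$ang_o3_p_op, zeta + P_GEOM$op_twist)
  op2 <- nerf_place(rib_i["C3'", ], rib_i["O3'", ], P, P_GEOM$p_op,
                    P_GEOM$ang_o3_p_op, zeta - P_GEOM$op_twist)
  xyz <- rbind(P = P, OP1 = op1, OP2 = op2, "O5'" = O5)
  colnames(xyz) <- c("x", "y", "z")
  failed <- vnorm(O5 - rib_j["C5'", ]) > CLOSE_GEOM$bl + 1.0
  energy <- b3$e[i3]
  if (failed) energy <- energy + CLOSURE_FAIL_PENALTY
  list(eps = eps, zeta = zeta, xyz = xyz, energy = energy,
       n_eval = n_eval, failed = failed)
}

CLOSURE_FAIL_PENALTY <- 50
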