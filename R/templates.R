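#' Idealized nucleotide geometry templates
#'
#' Average planar base geometries (regular-polygon idealization, bond
#' lengths near crystallographic means) expressed directly in the
#' base-local frame, plus a C3'-endo ribose conformer in the same frame.
#' Base atoms of a model are always placed from these templates; ribose
#' atoms come from rotamer conformers; phosphates are rebuilt from the
#' epsilon/zeta torsions.  All coordinates are in Angstrom.
#'
#' @name templates
#' @keywords internal
NULL

# ring construction constants
RING_BOND <- 1.38      # aromatic ring bond
GLYC_BOND <- 1.48      # C1'-N glycosidic bond
CO_BOND <- 1.23        # exocyclic C=O
CN_BOND <- 1.34        # exocyclic C-N

polygon_ring <- function(names, center, radius, angles_deg) {
  th <- deg2rad(angles_deg)
  m <- cbind(center[1L] + radius * cos(th),
             center[2L] + radius * sin(th),
             0)
  rownames(m) <- names
  colnames(m) <- c("x", "y", "z")
  m
}

# exocyclic substituent: radially outward from the ring center
exo_atom <- function(ring, center, attach, bond) {
  u <- ring[attach, ] - c(center, 0)
  p <- ring[attach, ] + bond * u / vnorm(u)
  p
}

build_pyrimidine <- function(type) {
  center <- c(GLYC_BOND + RING_BOND, 0)
  ring <- polygon_ring(c("N1", "C2", "N3", "C4", "C5", "C6"),
                       center, RING_BOND,
                       c(180, 120, 60, 0, 300, 240))
  o2 <- exo_atom(ring, center, "C2", CO_BOND)
  ext <- if (type == "C") {
    rbind(O2 = o2, N4 = exo_atom(ring, center, "C4", CN_BOND))
  } else {
    rbind(O2 = o2, O4 = exo_atom(ring, center, "C4", CO_BOND))
  }
  rbind(ring, ext)
}

build_purine <- function(type) {
  r5 <- RING_BOND / (2 * sin(pi / 5))
  center5 <- c(GLYC_BOND + r5, 0)
  ring5 <- polygon_ring(c("N9", "C4", "C5", "N7", "C8"),
                        center5, r5,
                        c(180, 108, 36, -36, -108))
  mid45 <- (ring5["C4", 1:2] + ring5["C5", 1:2]) / 2
  u <- mid45 - center5
  u <- u / sqrt(sum(u * u))
  center6 <- mid45 + RING_BOND * cos(pi / 6) * u
  a4 <- rad2deg(atan2(ring5["C4", 2L] - center6[2L],
                      ring5["C4", 1L] - center6[1L]))
  # hexagon C4 -> N3 -> C2 -> N1 -> C6 -> C5, sixty degrees apart,
  # stepping away from C5
  a5 <- rad2deg(atan2(ring5["C5", 2L] - center6[2L],
                      ring5["C5", 1L] - center6[1L]))
  step <- if (wrap180(a5 - a4) > 0) -60 else 60
  ring6 <- polygon_ring(c("N3", "C2", "N1", "C6"),
                        center6, RING_BOND,
                        a4 + step * (1:4))
  ext <- if (type == "A") {
    rbind(N6 = exo_atom(ring6, center6, "C6", CN_BOND))
  } else {
    rbind(O6 = exo_atom(ring6, center6, "C6", CO_BOND),
          N2 = exo_atom(ring6, center6, "C2", CN_BOND))
  }
  rbind(ring5, ring6, ext)
}

#' Base heavy-atom template in the base-local frame
#'
#' @param type base type "A", "C", "G" or "U"
#' @return named N x 3 matrix; C1' is at the origin, the base plane is
#'   z = 0, the frame axes are exactly those of [build_base_frame()]
#' @export
base_template <- function(type) {
  key <- paste0("base_", type)
  cached <- geometry_cache[[key]]
  if (!is.null(cached)) return(cached)
  m <- if (is_purine(type)) build_purine(type) else build_pyrimidine(type)
  m <- rbind("C1'" = c(0, 0, 0), m)
  colnames(m) <- c("x", "y", "z")
  geometry_cache[[key]] <- m
  m
}

geometry_cache <- new.env(parent = emptyenv())

# --- ribose -----------------------------------------------------------

# C3'-endo sugar built once by natural-extension placement in the
# base-local frame; torsion constants chosen to give an anti glycosidic
# angle (calibrated with the duplex generator), delta ~ 82 deg and a
# C3'-endo pucker.
RIBOSE_CHI <- -123.77

#' C3'-endo ribose conformer in the base-local frame
#'
#' The eight sugar atoms (C1', C2', C3', C4', O4', O2', O3', C5')
#' expressed in the local frame of an attached base of the given type.
#' This is the reference conformer used by the fixture generator and the
#' fallback rotamer when a library has a single entry.
#'
#' @param type base type
#' @param chi glycosidic torsion in degrees (O4'-C1'-N-C(4|2)), anti
#'   default
#' @return named 8 x 3 coordinate matrix
#' @export
ribose_template <- function(type, chi = RIBOSE_CHI) {
  key <- paste0("ribose_", type, "_", format(chi))
  cached <- geometry_cache[[key]]
  if (!is.null(cached)) return(cached)
  base <- base_template(type)
  n <- FRAME_ATOMS[[type]][1L]
  cn <- FRAME_ATOMS[[type]][2L]
  c1 <- base["C1'", ]
  # anchor O4' and C2' off the glycosidic bond, then rigidly fit the
  # canonical puckered ring onto the three anchors
  o4 <- nerf_place(base[cn, ], base[n, ], c1, 1.41, 108.2, chi)
  c2 <- nerf_place(base[cn, ], base[n, ], c1, 1.53, 113.0, chi - 119)
  ring <- canonical_ribose_ring()
  fit <- superpose_fit(ring[c("C1'", "O4'", "C2'"), ],
                       rbind(c1, o4, c2))
  m <- rt_apply(fit, ring)
  rownames(m) <- rownames(ring)
  colnames(m) <- c("x", "y", "z")
  geometry_cache[[key]] <- m
  m
}

#' Canonical C3'-endo ribose (eight atoms) in its own frame
#' @keywords internal
canonical_ribose_ring <- function() {
  cached <- geometry_cache[["canonical_ring"]]
  if (!is.null(cached)) return(cached)
  # ring C1', C2', C3', C4', O4' as a puckered pentagon with C3' at the
  # pucker apex (C3'-endo)
  j <- 0:4
  rho <- 1.25
  q <- 0.39
  theta <- deg2rad(90 - 72 * j)
  z <- -sqrt(2 / 5) * q * cos(4 * pi * j / 5 + 2 * pi / 5)
  ring <- cbind(rho * cos(theta), rho * sin(theta), z)
  rownames(ring) <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  c5 <- nerf_place(ring["C2'", ], ring["C3'", ], ring["C4'", ],
                   1.51, 116.0, RIBOSE_T_C5)
  o3 <- nerf_place(c5, ring["C4'", ], ring["C3'", ], 1.42, 110.0, 82.0)
  o2 <- nerf_place(ring["O4'", ], ring["C1'", ], ring["C2'", ],
                   1.41, 110.5, RIBOSE_T_O2)
  m <- rbind(ring, "O2'" = o2, "O3'" = o3, "C5'" = c5)
  geometry_cache[["canonical_ring"]] <- m
  m
}

# torsions selecting the exocyclic branch directions (calibrated so that
# the assembled nucleotide has D-ribose chirality, O2' on the face
# opposite the base and delta near its A-form value)
RIBOSE_T_C5 <- -155
RIBOSE_T_O2 <- 96

#' Sugar-pucker improper angle nu
#'
#' Dihedral between the C2'-C4'-O4' and C2'-C4'-C3' planes, the pucker
#' coordinate conditioning the torsion statistics; positive values
#' correspond to C3'-endo.
#'
#' @param xyz named coordinate matrix containing C2', C3', C4', O4'
#' @return angle in degrees
#' @export
pucker_nu <- function(xyz) {
  dihedral(xyz["O4'", ], xyz["C2'", ], xyz["C4'", ], xyz["C3'", ])
}

#' Glycosidic torsion chi of a residue
#' @keywords internal
residue_chi <- function(res) {
  n <- FRAME_ATOMS[[res$type]][1L]
  cn <- FRAME_ATOMS[[res$type]][2L]
  dihedral(res$xyz["O4'", ], res$xyz["C1'", ], res$xyz[n, ], res$xyz[cn, ])
}
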