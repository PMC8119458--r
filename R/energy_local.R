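#' Clash, rotamer and internal energies
#'
#' The local terms of the refinement score: an empirical repulsion for
#' atomic clashes, a negative-log-density ribose rotamer energy, and
#' the softened-harmonic bond/angle plus statistical torsion energies
#' of the phosphate closure.
#'
#' @name energy-local
NULL

#' Clash energy parameters
#' @param k_clash repulsion growth-rate parameter (supported range 2-5)
#' @param shell plateau shell width in Angstrom
#' @export
clash_params <- function(k_clash = 3, shell = 0.4) {
  stopifnot(k_clash >= 2, k_clash <= 5, shell > 0)
  list(k_clash = k_clash, shell = shell)
}

#' Pairwise clash energy (vectorized)
#'
#' Zero beyond the minimum-approach radius r0; a constant plateau of
#' (k * shell)^4 in the shell just inside r0; linear growth with slope
#' 4 (k * shell)^3 below that.  As printed the plateau makes the energy
#' step from 0 to the plateau value exactly at r0; the function is
#' continuous at r0 - shell.
#'
#' @param d atomic distance(s), Angstrom, > 0
#' @param r0 minimum-approach radius (scalar or vector)
#' @param params see [clash_params()]
#' @return non-negative energy, same length as `d`
#' @export
eclash <- function(d, r0, params = clash_params()) {
  if (any(d <= 0)) stop("eclash: non-positive distance")
  k <- params$k_clash; s <- params$shell
  plateau <- (k * s)^4
  slope <- 4 * (k * s)^3
  out <- numeric(length(d))
  r0 <- rep_len(r0, length(d))
  inner <- d <= r0 - s
  mid <- !inner & d <= r0
  out[mid] <- plateau
  out[inner] <- plateau - slope * (d[inner] - r0[inner] + s)
  out
}

ROT_KERNEL_WIDTH <- 0.15

#' Ribose rotamer energy
#'
#' Negative log of a kernel density over rotamer space relative to its
#' maximum: `E_rot(x) = -ln f(x) / f_max`, where the density sums
#' Gaussian kernels of width 0.15 A over the library conformers and the
#' distance between conformers is the RMS deviation of the eight ribose
#' atoms expressed in the base-local frame.  Zero at the densest
#' conformer, non-negative everywhere.
#'
#' @param ribose_local 8 x 3 matrix of ribose atoms in the base-local
#'   frame (rows ordered as in the library)
#' @param library a `rotamer_library`
#' @param type base type
#' @return energy >= 0
#' @export
erot <- function(ribose_local, library, type) {
  grp <- library$types[[type]]
  if (is.null(grp)) stop("empty rotamer library for base type ", type)
  f <- rot_density(as.numeric(ribose_local), grp)
  fmax <- rot_fmax(grp)
  -log(f / fmax)
}

#' Kernel density of a rotamer against a library group
#' @keywords internal
rot_density <- function(flat, grp) {
  d <- sqrt(rowSums(sweep(grp$flat, 2L, flat)^2) / 8)
  sum(grp$weights * exp(-0.5 * (d / ROT_KERNEL_WIDTH)^2)) * length(grp$weights)
}

#' Maximum library density (cached): the density at the densest stored
#' conformer
#' @keywords internal
rot_fmax <- function(grp) {
  if (!is.null(grp$fmax)) return(grp$fmax)
  vals <- vapply(seq_len(nrow(grp$flat)), function(i) {
    rot_density(grp$flat[i, ], grp)
  }, numeric(1L))
  max(vals)
}

#' Precompute cached rotamer density maxima
#' @keywords internal
finalize_rotamer_library <- function(library) {
  for (ty in names(library$types)) {
    grp <- library$types[[ty]]
    if (!is.null(grp)) {
      grp$fmax <- rot_fmax(grp)
      library$types[[ty]] <- grp
    }
  }
  library
}

#' Softened harmonic: quadratic core with linear wings
#'
#' u^2 on [-1, 1], continued linearly (slope +-2) outside so that the
#' function and its first derivative are continuous at |u| = 1.  Used
#' for the flexible O5'-C5' bond and its two flanking angles.
#'
#' @param u dimensionless strain (vectorized)
#' @return energy, same length as `u`
#' @export
softened_harmonic <- function(u) {
  out <- u * u
  hi <- u > 1
  lo <- u < -1
  out[hi] <- 2 * u[hi] - 1
  out[lo] <- -2 * u[lo] - 1
  out
}

#' Backbone torsion energy of a junction
#'
#' Sum of the three conditional negative-log probabilities
#' -ln P(eps, zeta | nu_i) - ln P(alpha | zeta, beta)
#' - ln P(beta, gamma | nu_i+1) from the corpus-derived tables.
#'
#' @param dihedrals named list or vector with nu_i, eps, zeta, alpha,
#'   beta, gamma, nu_j (degrees)
#' @param tables a `torsion_tables` object
#' @return finite energy (tables are smoothed)
#' @export
etorsion <- function(dihedrals, tables) {
  d <- as.list(dihedrals)
  etorsion_terms(d$nu_i, d$eps, d$zeta, d$alpha, d$beta, d$gamma,
                 d$nu_j, tables)
}
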