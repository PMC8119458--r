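#' Six-dimensional base-base statistical energy
#'
#' The orientation distribution of one base around another is estimated
#' by kernel density over the pseudo-atom distance-matrix metric, with
#' a flat-top radial kernel; for non-local pairs the density is
#' reweighted so that orientations backed by strong quantum-chemical
#' pair energies dominate orientations that are merely frequent.  The
#' energy is the negative log density scaled so its minimum hits a
#' prescribed reference depth, clipped at zero (statistical repulsion
#' is unreliable), and tabulated on the 6D grid (50 radial bins of
#' 0.3 A, 45 twist bins of 8 degrees, and a sphere codebook for each
#' direction).
#'
#' @name energy-bb
NULL

#' Base-base kernel parameters
#' @param flat_top flat-top radius (Angstrom)
#' @param width Gaussian width (Angstrom)
#' @export
bb_kernel_params <- function(flat_top = 0.15, width = 0.1) {
  stopifnot(flat_top > 0, width > 0)
  list(flat_top = flat_top, width = width)
}

#' Energy scaling configuration
#'
#' Reference depths the table minima are scaled to: -8.0 for non-local
#' pairs (separation > 2, anchored to the quantum pair-energy scale),
#' -4.0 for local pairs, and the 4.32 kcal/mol conversion between
#' quantum and statistical energies.
#' @param target_nonlocal,target_local table minima (negative)
#' @param qm_scale kcal/mol per statistical-energy unit
#' @export
scaling_config <- function(target_nonlocal = -8.0, target_local = -4.0,
                           qm_scale = 4.32) {
  stopifnot(target_nonlocal < 0, target_local < 0, qm_scale > 0)
  list(target_nonlocal = target_nonlocal, target_local = target_local,
       qm_scale = qm_scale)
}

bb_target <- function(scaling, sep) {
  if (sep == "2+") scaling$target_nonlocal else scaling$target_local
}

#' Flat-top radial kernel
#'
#' 1 for d below the flat-top radius, Gaussian decay beyond;
#' continuous at the boundary.
#'
#' @param d non-negative distance(s) in the DDM metric (Angstrom)
#' @param params see [bb_kernel_params()]
#' @return weights in (0, 1]
#' @export
kernel_h <- function(d, params = bb_kernel_params()) {
  if (any(d < 0)) stop("kernel_h: negative distance")
  w <- exp(-0.5 * ((d - params$flat_top) / params$width)^2)
  w[d <= params$flat_top] <- 1
  w
}

#' Kernel density of a configuration against a library group
#'
#' `f(x) = sum_i w_i h(DDM(x, x_i))`; with unit weights this is the raw
#' orientation distribution density.
#'
#' @param d16 flattened 4 x 4 cross-distance configuration
#' @param grp library group (as from [pair_group()]), or NULL
#' @param weights per-observation weights (default 1)
#' @param params kernel parameters
#' @return non-negative density (0 for an empty group)
#' @export
density_f <- function(d16, grp, weights = NULL,
                      params = bb_kernel_params()) {
  if (is.null(grp) || grp$n == 0L) return(0)
  d <- ddm_to_all(d16, grp$d16)
  h <- kernel_h(d, params)
  if (is.null(weights)) sum(h) else sum(weights * h)
}

#' Quantum reweighting factors for a library group
#'
#' `w(x_i) = exp(-E_QM(c(x_i)) / scale) / f(c(x_i))` where c(x_i) is
#' the cluster center nearest to observation x_i and f the unweighted
#' density at that center.  The density denominator is floored at 1e-6
#' so sparsely populated centers cannot produce unbounded weights.
#'
#' @param grp library group
#' @param clusters `orientation_clusters` of the same pair type
#' @param qm QM table entry: numeric vector of center energies
#'   (kcal/mol), one per cluster center
#' @param scaling see [scaling_config()]
#' @param params kernel parameters
#' @return per-observation weight vector
#' @export
qm_weights <- function(grp, clusters, qm, scaling = scaling_config(),
                       params = bb_kernel_params()) {
  stopifnot(length(qm) == nrow(clusters$centers))
  f_center <- vapply(seq_len(nrow(clusters$centers)), function(c) {
    density_f(clusters$centers[c, ], grp, params = params)
  }, numeric(1L))
  f_center <- pmax(f_center, 1e-6)
  idx <- nearest_center(clusters, grp$d16)
  exp(-qm[idx] / scaling$qm_scale) / f_center[idx]
}

R_BIN <- 0.3
R_NBIN <- 50L
W_BIN <- 8
W_NBIN <- 45L

#' Build the 6D energy table for one pair type and separation class
#'
#' Evaluates the (re)weighted kernel density at the representative
#' configuration of every grid cell near an observation, converts to
#' `E0 = -ln f'(x)/f_ref` with `f_ref` chosen so the minimum equals
#' the configured target depth, clips positives to zero and stores
#' only the negative cells (absent cells read as 0).
#'
#' @param library a `pair_library`
#' @param types base-type pair
#' @param sep separation class ("1", "2", "2+")
#' @param codebook a `sphere_codebook`
#' @param clusters optional `orientation_clusters` (used with `qm` for
#'   sep "2+")
#' @param qm optional numeric vector of center QM energies (kcal/mol)
#' @param scaling see [scaling_config()]
#' @param params kernel parameters
#' @param expand evaluate the +-1 radial and twist neighbours of every
#'   occupied cell as well (default TRUE)
#' @return an `energy_table_6d`
#' @export
build_bb_table <- function(library, types, sep, codebook,
                           clusters = NULL, qm = NULL,
                           scaling = scaling_config(),
                           params = bb_kernel_params(),
                           expand = TRUE) {
  grp <- pair_group(library, types, sep)
  tab <- structure(list(types = sort(types), sep = sep,
                        codebook = codebook,
                        cells = new.env(parent = emptyenv()),
                        target = bb_target(scaling, sep),
                        n_obs = if (is.null(grp)) 0L else grp$n),
                   class = "energy_table_6d")
  if (is.null(grp) || grp$n == 0L) {
    warning("empty library for ", canonical_pair(types[1L], types[2L]),
            " sep ", sep, ": all-zero table")
    return(tab)
  }
  weights <- if (sep == "2+" && !is.null(clusters) && !is.null(qm)) {
    qm_weights(grp, clusters, qm, scaling, params)
  } else {
    rep(1, grp$n)
  }
  ir <- pmin(R_NBIN, floor(grp$r / R_BIN) + 1L)
  iw <- pmin(W_NBIN, floor((grp$omega + 180) / W_BIN) + 1L)
  ci <- codebook_nearest(codebook, grp$dir_ij)
  cj <- codebook_nearest(codebook, grp$dir_ji)
  keys <- paste(ir, iw, ci, cj, sep = "|")
  if (expand) {
    for (dr in c(-1L, 0L, 1L)) for (dw in c(-1L, 0L, 1L)) {
      irn <- ir + dr
      iwn <- ((iw + dw - 1L) %% W_NBIN) + 1L
      ok <- irn >= 1L & irn <= R_NBIN
      keys <- c(keys, paste(irn[ok], iwn[ok], ci[ok], cj[ok], sep = "|"))
    }
  }
  keys <- unique(keys)
  parts <- matrix(as.integer(unlist(strsplit(keys, "|", fixed = TRUE))),
                  ncol = 4L, byrow = TRUE)
  f_vals <- vapply(seq_len(nrow(parts)), function(k) {
    density_f(cell_representative_d16(parts[k, ], codebook, tab$types),
              grp, weights, params)
  }, numeric(1L))
  fmax <- max(f_vals)
  if (fmax <= 0) return(tab)
  f_ref <- fmax * exp(tab$target)
  e0 <- -log(pmax(f_vals, .Machine$double.xmin) / f_ref)
  neg <- which(e0 < 0)
  for (k in neg) tab$cells[[keys[k]]] <- e0[k]
  tab
}

#' Representative configuration of a 6D grid cell (flattened)
#' @keywords internal
cell_representative_d16 <- function(cell, codebook, types) {
  r <- (cell[1L] - 0.5) * R_BIN
  omega <- -180 + (cell[2L] - 0.5) * W_BIN
  orient <- structure(list(r = r, omega = omega,
                           dir_ij = codebook$vectors[cell[3L], ],
                           dir_ji = codebook$vectors[cell[4L], ]),
                      class = "relative_orientation")
  fi <- base_frame(c(0, 0, 0), diag(3L))
  fj <- frame_from_orientation(fi, orient)
  pair_configuration(fi, fj, types)$d16
}

#' Interpolated lookup in a 6D energy table
#'
#' Bilinear interpolation over the radial and twist axes (twist
#' periodic) with nearest-codebook-cell resolution of the two
#' directions; 0 beyond the 15 A range and in unstored (non-negative)
#' cells.
#'
#' @param table an `energy_table_6d`
#' @param orient a `relative_orientation`
#' @return energy (<= 0)
#' @export
ebb_lookup <- function(table, orient) {
  if (orient$r >= R_NBIN * R_BIN) return(0)
  ci <- codebook_nearest(table$codebook, orient$dir_ij)
  cj <- codebook_nearest(table$codebook, orient$dir_ji)
  # centered coordinates on each axis
  x <- orient$r / R_BIN + 0.5
  y <- (orient$omega + 180) / W_BIN + 0.5
  i0 <- floor(x); ti <- x - i0
  j0 <- floor(y); tj <- y - j0
  val <- function(ir, iwraw) {
    if (ir < 1L || ir > R_NBIN) return(0)
    iw <- ((iwraw - 1L) %% W_NBIN) + 1L
    table$cells[[paste(ir, iw, ci, cj, sep = "|")]] %||% 0
  }
  (1 - ti) * ((1 - tj) * val(i0, j0) + tj * val(i0, j0 + 1L)) +
    ti * ((1 - tj) * val(i0 + 1L, j0) + tj * val(i0 + 1L, j0 + 1L))
}

#' Number of stored (negative) cells
#' @param table an `energy_table_6d`
#' @export
bb_table_size <- function(table) length(ls(table$cells))

#' Minimum stored energy of a table (0 when empty)
#' @param table an `energy_table_6d`
#' @export
bb_table_min <- function(table) {
  keys <- ls(table$cells)
  if (!length(keys)) return(0)
  min(vapply(keys, function(k) table$cells[[k]], numeric(1L)))
}
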