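#' Total refinement energy
#'
#' Assembly of the full score: base-base, base-oxygen and
#' oxygen-oxygen statistical terms over all residue pairs in range,
#' the clash repulsion over non-bonded atom pairs, the per-residue
#' ribose rotamer energy and the per-junction internal
#' (bond/angle/torsion) energy.  The decomposition is strictly
#' additive.
#'
#' @name scoring
NULL

#' Bundle of all statistical tables needed for scoring
#'
#' @param corpus list of `rna_structure` used for statistics
#' @param codebook_n sphere codebook size (2000 in the full-scale
#'   protocol; smaller for desk-scale corpora)
#' @param k_clusters orientation cluster centers per pair type for the
#'   QM reweighting (80 full scale)
#' @param qm_rule rule for the synthetic QM table, see [toy_qm_table()]
#'   (NULL disables reweighting)
#' @param seed RNG seed governing codebook and clustering
#' @param scaling see [scaling_config()]
#' @param max_rotamers rotamer library size cap
#' @param verbose print progress
#' @return a `refine_tables` bundle
#' @export
build_all_tables <- function(corpus, codebook_n = 200L,
                             k_clusters = 16L, qm_rule = "contact",
                             seed = 1L, scaling = scaling_config(),
                             max_rotamers = 1500L, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("collecting pair observations")
  library <- collect_pair_observations(corpus)
  say("collecting polar observations")
  polar <- collect_polar_observations(corpus)
  say("collecting rotamers and torsions")
  rot <- finalize_rotamer_library(collect_rotamers(corpus, max_rotamers))
  torsion <- collect_torsion_stats(corpus)
  say("estimating clash radii")
  clash <- estimate_r0(corpus)
  say("building sphere codebook")
  codebook <- generate_sphere_codebook(codebook_n, seed)
  bb <- new.env(parent = emptyenv())
  qm <- NULL
  for (tp in PAIR_TYPES) {
    types <- strsplit(tp, "")[[1L]]
    for (sep in c("1", "2", "2+")) {
      grp <- pair_group(library, types, sep)
      if (is.null(grp)) next
      clusters <- NULL; qmvec <- NULL
      if (sep == "2+" && !is.null(qm_rule) && grp$n >= k_clusters) {
        clusters <- cluster_orientations(library, types, sep,
                                         k = k_clusters, seed = seed)
        qmvec <- toy_qm_table(clusters, qm_rule)$energies
        qm[[tp]] <- list(clusters = clusters, energies = qmvec)
      }
      say("table ", tp, " sep ", sep, " (", grp$n, " obs)")
      bb[[paste0(tp, "|", sep)]] <-
        build_bb_table(library, types, sep, codebook, clusters, qmvec,
                       scaling)
    }
  }
  say("building polar tables")
  structure(list(bb = bb, polar = build_polar_tables(polar),
                 rot = rot, torsion = torsion, clash = clash,
                 codebook = codebook, scaling = scaling,
                 library = library, qm = qm,
                 version = TABLE_ARCHIVE_VERSION),
            class = "refine_tables")
}

TABLE_ARCHIVE_VERSION <- "1"

#' Base-base energy between two residues (canonical direction)
#' @keywords internal
ebb_pair <- function(fi, fj, ti, tj, sep, tables) {
  if (ti > tj) {
    tmp <- fi; fi <- fj; fj <- tmp
    tmp <- ti; ti <- tj; tj <- tmp
  }
  key <- paste0(ti, tj, "|", sep)
  tab <- tables$bb[[key]]
  if (is.null(tab)) return(0)
  if (vnorm(fj$origin - fi$origin) < DEGENERATE_TOL) return(0)
  orient <- relative_orientation(fi, fj)
  if (orient$r > PAIR_RANGE) return(0)
  ebb_lookup(tab, orient)
}

#' All interaction terms between a pair of residues
#'
#' Returns the summed base-base, base-oxygen, oxygen-oxygen and clash
#' energies between residues `i` and `j` of a structure (frames
#' precomputed by the caller).
#' @keywords internal
residue_pair_energy <- function(res_i, res_j, frame_i, frame_j,
                                neighbour, tables,
                                params = clash_params(),
                                w_clash = 1) {
  out <- c(bb = 0, bo = 0, oo = 0, clash = 0)
  dorig <- vnorm(frame_j$origin - frame_i$origin)
  # beyond any term's reach (origins > 22 A): atoms sit within ~8.5 A
  # of their origin and no contact term extends past 5 A
  if (dorig > 22) return(out)
  sepc <- separation_class(res_i, res_j)
  if (dorig <= PAIR_RANGE) {
    out["bb"] <- ebb_pair(frame_i, frame_j, res_i$type, res_j$type,
                          sepc, tables)
  }
  out["bo"] <- bo_pair_energy(res_i, res_j, frame_i, tables) +
    bo_pair_energy(res_j, res_i, frame_j, tables)
  out["oo"] <- oo_pair_energy(res_i, res_j, tables)
  out["clash"] <- w_clash * clash_pair_energy(res_i, res_j, frame_i,
                                              frame_j, neighbour,
                                              tables$clash, params)
  out
}

#' Attach derived per-residue data used by the pair terms
#'
#' Computed once per residue conformation and reused across all pair
#' evaluations: base heavy-atom block, pseudo-atoms, polar atoms,
#' backbone oxygens with their anchors, and hydroxyl/phosphate sites.
#' @keywords internal
residue_with_cache <- function(res, frame) {
  if (!is.null(res$cache)) return(res)
  nm <- rownames(res$xyz)
  bn <- base_atom_names(res$type)
  ox <- intersect(BACKBONE_OXYGENS, nm)
  ox <- ox[OXYGEN_ANCHOR[ox] %in% nm]
  pol <- intersect(BASE_POLAR_ATOMS[[res$type]], nm)
  oo_names <- intersect(c("O2'", "OP1", "OP2"), nm)
  oo_names <- oo_names[OXYGEN_ANCHOR[oo_names] %in% nm]
  res$cache <- list(
    base_xyz = res$xyz[bn, , drop = FALSE],
    pseudo = pseudo_atoms(frame),
    pol_xyz = res$xyz[pol, , drop = FALSE],
    ox = ox,
    O = res$xyz[ox, , drop = FALSE],
    anchors = res$xyz[OXYGEN_ANCHOR[ox], , drop = FALSE],
    oo_names = oo_names,
    oo_O = res$xyz[oo_names, , drop = FALSE],
    oo_anchor = res$xyz[OXYGEN_ANCHOR[oo_names], , drop = FALSE],
    oo_kind = ifelse(oo_names == "O2'", "O2'", "OP"))
  res
}

#' Base(i)-oxygen(j) energies
#'
#' Vectorized over the oxygens of residue j: one distance matrix gives
#' the gate distances, one the pseudo-atom representation, and the
#' kernel densities are evaluated in a single batched call per oxygen
#' type.
#' @keywords internal
bo_pair_energy <- function(res_b, res_o, frame_b, tables) {
  cb <- res_b$cache
  co <- res_o$cache
  if (!length(co$ox)) return(0)
  nb <- nrow(cb$base_xyz)
  np <- nrow(cb$pol_xyz)
  # one distance matrix for base block, pseudo-atoms and polar atoms
  ALL <- cross_dist(rbind(cb$base_xyz, cb$pseudo, cb$pol_xyz), co$O)
  Dbase <- ALL[seq_len(nb), , drop = FALSE]
  dmin <- do.call(pmin, lapply(seq_len(nb), function(r) Dbase[r, ]))
  sel <- which(dmin <= BO_RANGE)
  if (!length(sel)) return(0)
  D4 <- ALL[nb + 1:4, sel, drop = FALSE]
  PD <- ALL[nb + 4L + seq_len(np), sel, drop = FALSE]
  p <- tables$polar$params
  e <- 0
  for (k in seq_along(sel)) {
    a <- co$ox[sel[k]]
    otype <- oxygen_type(a)
    grp <- tables$polar$bo[[paste0(res_b$type, "|", otype)]]
    if (is.null(grp)) next
    s_ang <- if (otype %in% p$gated_oxygens) {
      rng <- tables$polar$angles[[otype]]
      close_pol <- which(PD[, k] <= HB_RANGE)
      if (is.null(rng) || !length(close_pol)) 0
      else {
        an_xyz <- co$anchors[sel[k], ]
        max(vapply(close_pol, function(pp) {
          angle_score_s(bond_angle(cb$pol_xyz[pp, ], co$O[sel[k], ],
                                   an_xyz), rng)
        }, numeric(1L)))
      }
    } else 1
    if (s_ang == 0) next
    w <- decay_weight(dmin[sel[k]], p$bo_mid, p$bo_rate)
    f <- kde_group_density(D4[, k], grp$d4, p$bo_width)
    if (f <= 0) next
    e <- e - w * s_ang * log(f / grp$f_ref)
  }
  e
}

#' Oxygen-oxygen energies between two residues
#' @keywords internal
oo_pair_energy <- function(res_i, res_j, tables) {
  ci <- res_i$cache; cj <- res_j$cache
  if (!length(ci$oo_names) || !length(cj$oo_names)) return(0)
  D <- cross_dist(ci$oo_O, cj$oo_O)
  hits <- which(D <= OO_RANGE, arr.ind = TRUE)
  if (!nrow(hits)) return(0)
  e <- 0
  for (h in seq_len(nrow(hits))) {
    a <- hits[h, 1L]; b <- hits[h, 2L]
    cls <- oo_class(ci$oo_kind[a], cj$oo_kind[b])
    quad <- rbind(ci$oo_anchor[a, ], ci$oo_O[a, ],
                  cj$oo_O[b, ], cj$oo_anchor[b, ])
    e <- e + eoo(list(class = cls, d = D[a, b], d6 = quad_d6(quad)),
                 tables$polar)
  }
  e
}

#' Clash energy between the atoms of two residues (or within one)
#'
#' Distances are screened in one vectorized pass against the largest
#' possible radius; only the few violating candidates go through the
#' per-pair (possibly orientation-resolved) radius lookup.
#' @keywords internal
clash_pair_energy <- function(res_i, res_j, frame_i, frame_j, neighbour,
                              table, params = clash_params()) {
  same <- is.null(res_j)
  A <- res_i$xyz
  B <- if (same) res_i$xyz else res_j$xyz
  pc <- clash_pair_setup(res_i$type, if (same) NULL else res_j$type,
                         rownames(A), rownames(B), neighbour,
                         same, res_i, res_j, table)
  D <- cross_dist(A, B)
  hit <- which(D < pc$screen, arr.ind = TRUE)
  if (!nrow(hit)) return(0)
  e <- 0
  for (h in seq_len(nrow(hit))) {
    ia <- hit[h, 1L]; ib <- hit[h, 2L]
    d <- max(D[ia, ib], 1e-6)
    r0 <- pc$r0[ia, ib]
    if (pc$orient[ia, ib]) {
      # orientation-resolved radius for the base-atom partner
      if (pc$base_j[ib]) {
        loc <- as.numeric(t(frame_j$axes) %*% (A[ia, ] - frame_j$origin))
        r0 <- r0_lookup_oriented(table, pc$cls_i[ia], res_j$type,
                                 rownames(B)[ib], loc)
      } else {
        loc <- as.numeric(t(frame_i$axes) %*% (B[ib, ] - frame_i$origin))
        r0 <- r0_lookup_oriented(table, pc$cls_j[ib], res_i$type,
                                 rownames(A)[ia], loc)
      }
    }
    if (d < r0) e <- e + eclash(d, r0, params)
  }
  e
}

#' Precomputed per-type-pair clash data (exclusions, isotropic radii,
#' screening thresholds), keyed by types, atom sets and context
#' @keywords internal
clash_pair_setup <- function(ti, tj, nm_i, nm_j, neighbour, same,
                             res_i, res_j, table) {
  key <- paste0("clash_setup|", ti, "|", tj %||% "", "|", neighbour,
                "|", same, "|",
                if (!same && !is.null(res_j) &&
                    res_i$resno > res_j$resno) "swap" else "fwd", "|",
                paste(nm_i, collapse = ","), "|",
                paste(nm_j, collapse = ","))
  cached <- geometry_cache[[key]]
  if (!is.null(cached)) return(cached)
  ni <- length(nm_i); nj <- length(nm_j)
  excl <- if (same) {
    bonded_pairs(ti)
  } else if (neighbour) {
    if (res_i$resno < res_j$resno) bonded_pairs(ti, tj)
    else bonded_pairs(tj, ti)
  } else NULL
  swap <- !same && neighbour && res_i$resno > res_j$resno
  base_i <- nm_i %in% base_atom_names(ti)
  base_j <- if (same) base_i else nm_j %in% base_atom_names(tj)
  cls_i <- vapply(seq_len(ni), function(k) {
    atom_class(nm_i[k], base_i[k])
  }, character(1L))
  cls_j <- vapply(seq_len(nj), function(k) {
    atom_class(nm_j[k], base_j[k])
  }, character(1L))
  r0 <- matrix(0, ni, nj)
  orient <- matrix(FALSE, ni, nj)
  screen <- matrix(0, ni, nj)
  for (a in seq_len(ni)) {
    for (b in seq_len(nj)) {
      if (same && b <= a) next
      if (!is.null(excl)) {
        k1 <- if (same) paste0("i:", nm_i[a], "|i:", nm_i[b])
              else if (swap) paste0("j:", nm_i[a], "|i:", nm_j[b])
              else paste0("i:", nm_i[a], "|j:", nm_j[b])
        if (isTRUE(excl[[k1]])) next
      }
      r0[a, b] <- r0_lookup(table, cls_i[a], cls_j[b])
      orient[a, b] <- !same && (base_i[a] || base_j[b])
      # screening must cover the largest radius an oriented cell can
      # return (the element-pair cap)
      screen[a, b] <- if (orient[a, b]) {
        max(r0[a, b], r0_cap(cls_i[a], cls_j[b]))
      } else r0[a, b]
    }
  }
  out <- list(r0 = r0, orient = orient, screen = screen,
              base_j = base_j, cls_i = cls_i, cls_j = cls_j)
  geometry_cache[[key]] <- out
  out
}

#' Internal energy of a junction as placed
#' @keywords internal
junction_internal_energy <- function(res_i, res_j, tables = NULL) {
  need <- c("P", "O5'", "C5'", "C4'", "O4'")
  if (!all(need %in% rownames(res_j$xyz))) return(NA_real_)
  P <- res_j$xyz["P", ]; O5 <- res_j$xyz["O5'", ]
  eps <- dihedral(res_i$xyz["C2'", ], res_i$xyz["C3'", ],
                  res_i$xyz["O3'", ], P)
  zeta <- dihedral(res_i$xyz["C3'", ], res_i$xyz["O3'", ], P, O5)
  closure_internal_energy(res_i$xyz, res_j$xyz, matrix(P, 1L),
                          matrix(O5, 1L), eps, zeta,
                          if (!is.null(tables)) tables$torsion)
}

#' Score a structure with the full energy decomposition
#'
#' @param x an `rna_structure`
#' @param tables a `refine_tables` bundle
#' @param w_clash,w_internal weights on the clash and internal terms
#'   (ramped during annealing; 1 for scoring)
#' @param params clash parameters
#' @return an `energy_breakdown`: E_bb, E_bo, E_oo, E_rot, E_internal,
#'   E_clash and their total
#' @export
total_energy <- function(x, tables, w_clash = 1, w_internal = 1,
                         params = clash_params()) {
  res <- x$residues
  n <- length(res)
  frames <- structure_frames(x)
  for (i in seq_len(n)) res[[i]] <- residue_with_cache(res[[i]], frames[[i]])
  terms <- c(bb = 0, bo = 0, oo = 0, clash = 0)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        nb <- is_chain_neighbour(res[[i]], res[[j]])
        terms <- terms + residue_pair_energy(res[[i]], res[[j]],
                                             frames[[i]], frames[[j]],
                                             nb, tables, params)
      }
    }
  }
  # intra-residue clashes
  e_intra <- sum(vapply(seq_len(n), function(i) {
    clash_pair_energy(res[[i]], NULL, frames[[i]], NULL, FALSE,
                      tables$clash, params)
  }, numeric(1L)))
  e_rot <- sum(vapply(seq_len(n), function(i) {
    if (!all(RIBOSE_ATOMS %in% rownames(res[[i]]$xyz))) return(0)
    erot(residue_ribose_local(res[[i]], frames[[i]]), tables$rot,
         res[[i]]$type)
  }, numeric(1L)))
  e_int <- 0
  for (i in seq_len(max(n - 1L, 0L))) {
    if (res[[i]]$chain != res[[i + 1L]]$chain) next
    v <- junction_internal_energy(res[[i]], res[[i + 1L]], tables)
    if (!is.na(v)) e_int <- e_int + v
  }
  e_clash <- w_clash * (terms[["clash"]] + e_intra)
  # terms["clash"] already carries w_clash = 1 from residue_pair_energy
  breakdown <- c(E_bb = terms[["bb"]], E_bo = terms[["bo"]],
                 E_oo = terms[["oo"]], E_rot = e_rot,
                 E_internal = w_internal * e_int,
                 E_clash = e_clash)
  structure(list(terms = breakdown, total = sum(breakdown)),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  for (k in names(x$terms)) {
    cat(sprintf("%-11s %10.4f\n", k, x$terms[k]))
  }
  cat(sprintf("%-11s %10.4f\n", "total", x$total))
  invisible(x)
}
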