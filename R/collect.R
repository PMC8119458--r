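#' Statistics harvested from a structure corpus
#'
#' Collectors that turn a corpus of RNA structures into the observation
#' libraries behind every statistical energy term: base-pair
#' orientations by separation class, base-oxygen and oxygen-oxygen
#' contacts, ribose rotamers, backbone-torsion triples and
#' minimum-approach (clash) radii.
#'
#' @name collectors
NULL

PAIR_RANGE <- 15       # max origin-origin distance for an observation
BO_RANGE <- 5          # collection range for base-oxygen contacts
OO_RANGE <- 4.5        # collection range for oxygen-oxygen contacts
HB_RANGE <- 3.5        # donor-acceptor range used for theta statistics

#' The ten unordered base-pair types, canonical alphabetical keys
#' @keywords internal
PAIR_TYPES <- c("AA", "AC", "AG", "AU", "CC", "CG", "CU", "GG", "GU", "UU")

canonical_pair <- function(t1, t2) paste0(sort(c(t1, t2)), collapse = "")

#' Flip an observation so its types are in canonical order
#'
#' The as-observed direction is preserved in `orient_fwd` / `d16_fwd`
#' (used by move-set construction); the canonical fields feed the
#' densities.
#' @keywords internal
canonicalize_obs <- function(obs) {
  if (is.null(obs$orient_fwd)) obs$orient_fwd <- obs$orient
  if (is.null(obs$d16_fwd)) obs$d16_fwd <- obs$d16
  if (is.null(obs$rel)) obs$rel <- NA_integer_
  if (obs$types[1L] <= obs$types[2L]) return(obs)
  o <- obs$orient
  obs$orient <- structure(list(r = o$r, omega = o$omega,
                               dir_ij = o$dir_ji, dir_ji = o$dir_ij),
                          class = "relative_orientation")
  obs$d16 <- as.numeric(t(matrix(obs$d16, 4L, 4L)))
  obs$types <- rev(obs$types)
  obs
}

#' Construct a pair library from a list of observations
#' @keywords internal
new_pair_library <- function(obs) {
  obs <- lapply(obs, canonicalize_obs)
  keys <- vapply(obs, function(o) {
    paste0(paste0(o$types, collapse = ""), "|", o$sep)
  }, character(1L))
  groups <- new.env(parent = emptyenv())
  for (k in unique(keys)) {
    sel <- obs[keys == k]
    groups[[k]] <- list(
      d16 = do.call(rbind, lapply(sel, function(o) o$d16)),
      r = vapply(sel, function(o) o$orient$r, numeric(1L)),
      omega = vapply(sel, function(o) o$orient$omega, numeric(1L)),
      dir_ij = do.call(rbind, lapply(sel, function(o) o$orient$dir_ij)),
      dir_ji = do.call(rbind, lapply(sel, function(o) o$orient$dir_ji)),
      n = length(sel))
  }
  structure(list(obs = obs, groups = groups), class = "pair_library")
}

#' @export
print.pair_library <- function(x, ...) {
  keys <- sort(ls(x$groups))
  cat("pair_library:", length(x$obs), "observations\n")
  for (k in keys) cat(" ", k, ":", x$groups[[k]]$n, "\n")
  invisible(x)
}

#' Observations of one pair type and separation class
#' @param library a `pair_library`
#' @param types character 2-vector (canonicalized internally)
#' @param sep "1", "2" or "2+"
#' @return group record (NULL when empty)
#' @export
pair_group <- function(library, types, sep) {
  library$groups[[paste0(canonical_pair(types[1L], types[2L]), "|", sep)]]
}

#' Collect base-pair orientation observations from a corpus
#'
#' Every ordered residue pair whose frame origins are within 15 A is
#' recorded once per direction, tagged with its separation class
#' (intra-chain index distance 1 or 2; everything else, including
#' inter-chain pairs, is non-local "2+").
#'
#' @param corpus list of `rna_structure` objects
#' @return a `pair_library`
#' @export
collect_pair_observations <- function(corpus) {
  if (length(corpus) == 0L) stop("empty corpus")
  obs <- list()
  for (s in corpus) {
    frames <- structure_frames(s)
    n <- length(frames)
    if (n < 2L) next
    orig <- do.call(rbind, lapply(frames, function(f) f$origin))
    D <- as.matrix(stats::dist(orig))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j || D[i, j] > PAIR_RANGE) next
        ri <- s$residues[[i]]; rj <- s$residues[[j]]
        rel <- if (ri$chain == rj$chain) rj$resno - ri$resno
               else NA_integer_
        obs[[length(obs) + 1L]] <- list(
          types = c(ri$type, rj$type),
          sep = separation_class(ri, rj),
          rel = as.integer(rel),
          source = s$id,
          orient = relative_orientation(frames[[i]], frames[[j]]),
          d16 = pair_configuration(frames[[i]], frames[[j]],
                                   c(ri$type, rj$type))$d16)
      }
    }
  }
  new_pair_library(obs)
}

#' Oxygen type of a backbone oxygen atom (OP merges OP1 and OP2)
#' @keywords internal
oxygen_type <- function(atom) {
  if (atom %in% c("OP1", "OP2")) "OP" else atom
}

#' Heavy atom bonded to each backbone oxygen (used for the theta angle)
#' @keywords internal
OXYGEN_ANCHOR <- c("OP1" = "P", "OP2" = "P", "O2'" = "C2'",
                   "O3'" = "C3'", "O4'" = "C4'", "O5'" = "C5'")

#' Base nitrogen/oxygen atoms that can hydrogen bond, per base type
#' @keywords internal
BASE_POLAR_ATOMS <- list(
  A = c("N1", "N3", "N6", "N7"),
  G = c("N1", "N2", "N3", "N7", "O6"),
  C = c("N3", "N4", "O2"),
  U = c("N3", "O2", "O4")
)

#' Collect base-oxygen and oxygen-oxygen contact observations
#'
#' Base-oxygen contacts record the four distances from the oxygen to
#' the base's pseudo-atoms, the minimum distance to any base heavy atom
#' and the hydrogen-bond angles theta (base N/O -- oxygen -- anchor C
#' or P) for base polar atoms in range.  Oxygen-oxygen contacts cover
#' the three hydroxyl/phosphate classes, each reduced to the six
#' pairwise distances among its four defining atoms.
#'
#' @param corpus list of `rna_structure` objects
#' @return a `polar_library` with components `bo` and `oo`
#' @export
collect_polar_observations <- function(corpus) {
  if (length(corpus) == 0L) stop("empty corpus")
  bo <- list(); oo <- list()
  for (s in corpus) {
    res <- s$residues
    n <- length(res)
    frames <- structure_frames(s)
    pseudo <- lapply(frames, pseudo_atoms)
    for (i in seq_len(n)) {
      base_xyz <- res[[i]]$xyz[base_atom_names(res[[i]]$type), ,
                               drop = FALSE]
      for (j in seq_len(n)) {
        if (i == j) next
        ox <- intersect(BACKBONE_OXYGENS, rownames(res[[j]]$xyz))
        for (a in ox) {
          o_xyz <- res[[j]]$xyz[a, ]
          dmin <- min(rows_norm(sweep(base_xyz, 2L, o_xyz)))
          if (dmin > BO_RANGE) next
          anchor <- OXYGEN_ANCHOR[[a]]
          if (!anchor %in% rownames(res[[j]]$xyz)) next
          an_xyz <- res[[j]]$xyz[anchor, ]
          pol <- intersect(BASE_POLAR_ATOMS[[res[[i]]$type]],
                           rownames(res[[i]]$xyz))
          pd <- rows_norm(sweep(res[[i]]$xyz[pol, , drop = FALSE],
                                2L, o_xyz))
          close_pol <- pol[pd <= HB_RANGE]
          thetas <- vapply(close_pol, function(p) {
            bond_angle(res[[i]]$xyz[p, ], o_xyz, an_xyz)
          }, numeric(1L))
          bo[[length(bo) + 1L]] <- list(
            base = res[[i]]$type, otype = oxygen_type(a),
            d4 = as.numeric(rows_norm(sweep(pseudo[[i]], 2L, o_xyz))),
            dmin = dmin, thetas = thetas, source = s$id)
        }
      }
    }
    # oxygen-oxygen contacts
    osites <- oo_sites(s)
    if (nrow(osites$tab) >= 2L) {
      for (ii in seq_len(nrow(osites$tab) - 1L)) {
        for (jj in (ii + 1L):nrow(osites$tab)) {
          ri <- osites$tab$res[ii]; rj <- osites$tab$res[jj]
          if (ri == rj) next
          d <- vnorm(osites$o[ii, ] - osites$o[jj, ])
          if (d > OO_RANGE) next
          cls <- oo_class(osites$tab$kind[ii], osites$tab$kind[jj])
          if (is.na(cls)) next
          quad <- rbind(osites$anchor[ii, ], osites$o[ii, ],
                        osites$o[jj, ], osites$anchor[jj, ])
          oo[[length(oo) + 1L]] <- list(
            class = cls, d = d, d6 = quad_d6(quad), source = s$id)
        }
      }
    }
  }
  structure(list(bo = bo, oo = oo), class = "polar_library")
}

#' Hydroxyl and phosphate oxygen sites of a structure
#' @keywords internal
oo_sites <- function(s) {
  tab <- NULL; o <- NULL; anchor <- NULL
  for (i in seq_along(s$residues)) {
    xyz <- s$residues[[i]]$xyz
    for (a in intersect(c("O2'", "OP1", "OP2"), rownames(xyz))) {
      kind <- if (a == "O2'") "O2'" else "OP"
      an <- OXYGEN_ANCHOR[[a]]
      if (!an %in% rownames(xyz)) next
      tab <- rbind(tab, data.frame(res = i, atom = a, kind = kind))
      o <- rbind(o, xyz[a, ])
      anchor <- rbind(anchor, xyz[an, ])
    }
  }
  if (is.null(tab)) tab <- data.frame(res = integer(), atom = character(),
                                      kind = character())
  list(tab = tab, o = o, anchor = anchor)
}

oo_class <- function(k1, k2) {
  key <- paste0(sort(c(k1, k2)), collapse = "-")
  switch(key, "O2'-O2'" = "O2'-O2'", "O2'-OP" = "O2'-OP",
         "OP-OP" = "OP-OP", NA_character_)
}

#' Six pairwise distances of a four-atom hydrogen-bond configuration
#' @keywords internal
quad_d6 <- function(quad) as.numeric(stats::dist(quad))

#' Heavy atoms belonging to the base moiety
#' @keywords internal
base_atom_names <- function(type) {
  setdiff(rownames(base_template(type)), "C1'")
}

#' Collect ribose rotamer conformers from a corpus
#'
#' Riboses are re-expressed in their base-local frame; the library
#' stores the eight-atom local coordinates plus the glycosidic torsion
#' chi and the pucker improper nu for each conformer, per base type.
#' When a corpus provides more conformers than `max_rotamers` they are
#' thinned deterministically to that size.
#'
#' @param corpus list of `rna_structure` objects
#' @param max_rotamers library size cap per base type (default 1500)
#' @return a `rotamer_library`
#' @export
collect_rotamers <- function(corpus, max_rotamers = 1500L) {
  if (length(corpus) == 0L) stop("empty corpus")
  by_type <- list(A = list(), C = list(), G = list(), U = list())
  for (s in corpus) {
    for (res in s$residues) {
      if (!all(RIBOSE_ATOMS %in% rownames(res$xyz))) next
      fr <- build_base_frame(res)
      loc <- residue_ribose_local(res, fr)
      by_type[[res$type]][[length(by_type[[res$type]]) + 1L]] <- list(
        local = loc, chi = residue_chi(res), nu = pucker_nu(res$xyz),
        source = s$id)
    }
  }
  lib <- lapply(by_type, function(lst) {
    if (length(lst) == 0L) return(NULL)
    if (length(lst) > max_rotamers) {
      keep <- round(seq(1L, length(lst), length.out = max_rotamers))
      lst <- lst[keep]
    }
    flat <- do.call(rbind, lapply(lst, function(x) as.numeric(x$local)))
    list(conformers = lst, flat = flat,
         weights = rep(1 / length(lst), length(lst)))
  })
  structure(list(types = lib), class = "rotamer_library")
}

TORSION_BIN <- 10  # degrees

angle_bin <- function(x) pmin(36L, pmax(1L, floor((x + 180) / TORSION_BIN) + 1L))

#' Pucker region of the improper nu (two-region split)
#' @keywords internal
pucker_region <- function(nu) ifelse(nu < 0, 1L, 2L)

#' Collect backbone torsion statistics from a corpus
#'
#' For every intact junction i -> i+1 (P bonded to O3' within the
#' chain-break limit) the seven angles nu_i, eps_i, zeta_i, alpha_i+1,
#' beta_i+1, gamma_i+1, nu_i+1 are recorded and binned (10 degree bins,
#' nu reduced to its two pucker regions) into three conditional tables
#' P(eps, zeta | nu), P(alpha | zeta, beta) and P(beta, gamma | nu),
#' each with add-one smoothing so the torsion energy stays finite.
#'
#' @param corpus list of `rna_structure` objects
#' @return a `torsion_tables` object
#' @export
collect_torsion_stats <- function(corpus) {
  if (length(corpus) == 0L) stop("empty corpus")
  rows <- NULL
  for (s in corpus) {
    res <- s$residues
    for (i in seq_len(length(res) - 1L)) {
      a <- res[[i]]; b <- res[[i + 1L]]
      if (a$chain != b$chain || b$resno != a$resno + 1L) next
      need_a <- c("C2'", "C3'", "O3'", RIBOSE_ATOMS)
      need_b <- c("P", "O5'", "C5'", "C4'", "O4'", RIBOSE_ATOMS)
      if (!all(need_a %in% rownames(a$xyz))) next
      if (!all(need_b %in% rownames(b$xyz))) next
      if (vnorm(b$xyz["P", ] - a$xyz["O3'", ]) > CHAIN_BREAK_P_O3) next
      rows <- rbind(rows, c(
        nu_i = pucker_nu(a$xyz),
        eps = dihedral(a$xyz["C2'", ], a$xyz["C3'", ], a$xyz["O3'", ],
                       b$xyz["P", ]),
        zeta = dihedral(a$xyz["C3'", ], a$xyz["O3'", ], b$xyz["P", ],
                        b$xyz["O5'", ]),
        alpha = dihedral(a$xyz["O3'", ], b$xyz["P", ], b$xyz["O5'", ],
                         b$xyz["C5'", ]),
        beta = dihedral(b$xyz["P", ], b$xyz["O5'", ], b$xyz["C5'", ],
                        b$xyz["C4'", ]),
        gamma = dihedral(b$xyz["O5'", ], b$xyz["C5'", ], b$xyz["C4'", ],
                         b$xyz["O4'", ]),
        nu_j = pucker_nu(b$xyz)))
    }
  }
  nb <- 360L / TORSION_BIN
  t_ez <- array(1, dim = c(2L, nb, nb))      # P(eps, zeta | nu region)
  t_a <- array(1, dim = c(nb, nb, nb))       # P(alpha | zeta, beta)
  t_bg <- array(1, dim = c(2L, nb, nb))      # P(beta, gamma | nu region)
  if (!is.null(rows)) {
    for (k in seq_len(nrow(rows))) {
      r <- rows[k, ]
      t_ez[pucker_region(r["nu_i"]), angle_bin(r["eps"]),
           angle_bin(r["zeta"])] <-
        t_ez[pucker_region(r["nu_i"]), angle_bin(r["eps"]),
             angle_bin(r["zeta"])] + 1
      t_a[angle_bin(r["zeta"]), angle_bin(r["beta"]),
          angle_bin(r["alpha"])] <-
        t_a[angle_bin(r["zeta"]), angle_bin(r["beta"]),
            angle_bin(r["alpha"])] + 1
      t_bg[pucker_region(r["nu_j"]), angle_bin(r["beta"]),
           angle_bin(r["gamma"])] <-
        t_bg[pucker_region(r["nu_j"]), angle_bin(r["beta"]),
             angle_bin(r["gamma"])] + 1
    }
  }
  # normalize each conditional slice
  for (g in 1:2) {
    t_ez[g, , ] <- t_ez[g, , ] / sum(t_ez[g, , ])
    t_bg[g, , ] <- t_bg[g, , ] / sum(t_bg[g, , ])
  }
  for (z in seq_len(nb)) for (b in seq_len(nb)) {
    t_a[z, b, ] <- t_a[z, b, ] / sum(t_a[z, b, ])
  }
  structure(list(ez = t_ez, a = t_a, bg = t_bg,
                 n_obs = if (is.null(rows)) 0L else nrow(rows),
                 raw = rows),
            class = "torsion_tables")
}

#' Torsion energy terms for one junction (vectorized)
#' @keywords internal
etorsion_terms <- function(nu_i, eps, zeta, alpha, beta, gamma, nu_j,
                           tables) {
  gi <- pucker_region(nu_i)
  gj <- pucker_region(nu_j)
  be <- angle_bin(eps); bz <- angle_bin(zeta); ba <- angle_bin(alpha)
  bb <- angle_bin(beta); bg <- angle_bin(gamma)
  n <- length(eps)
  e1 <- -log(tables$ez[cbind(rep(gi, n), be, bz)])
  e2 <- -log(tables$a[cbind(bz, bb, ba)])
  e3 <- -log(tables$bg[cbind(rep(gj, n), bb, bg)])
  e1 + e2 + e3
}
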