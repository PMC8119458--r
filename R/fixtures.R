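#' Deterministic synthetic fixtures
#'
#' Generators for ideal A-form duplexes, tetraloop-like hairpin toys,
#' noisy decoys and planted-mode pair libraries.  Every generator takes
#' a seed and is bit-reproducible; together the helix + hairpin corpus
#' populates every statistics class the energy tables need, so the full
#' pipeline can be built and exercised without any external data.
#'
#' @name fixtures
NULL

# Helical parameters of the idealized duplex generator.  Starting from
# standard A-form values, the displacement of the pair from the helix
# axis (along the pseudo-dyad), the two pair-tilt angles, the
# glycosidic torsion and twist/rise were re-calibrated once against the
# idealized nucleotide templates by minimizing the phosphate-closure
# strain of both strands subject to steric (>= 2.9 A between
# non-bonded residues) and stacking (3.2-3.8 A) constraints.  The
# result is a right-handed, sterically clean duplex with canonical
# hydrogen bonding whose backbone closes with near-zero internal
# energy.
HELIX_TWIST <- 27.3754   # degrees per step
HELIX_RISE <- 2.7169     # Angstrom per step
HELIX_SHIFT_Y <- 9.3191  # pair displacement along the pseudo-dyad
HELIX_TILT_X <- 0.4265   # pair tilt about x, degrees
HELIX_TILT_Y <- -53.034  # pair tilt about y, degrees

helix_slot_transform <- function(k) {
  rigid_transform(rot_axis(c(0, 0, 1), deg2rad(k * HELIX_TWIST)),
                  c(0, 0, k * HELIX_RISE))
}

# frame of the strand-1 (side = 1) or strand-2 (side = 2) base occupying
# helical slot k of a canonical pair t1:t2
helix_slot_frame <- function(k, t1, t2, side) {
  pf <- wc_pair_frames(t1, t2)[[side]]
  M <- rot_axis(c(1, 0, 0), deg2rad(HELIX_TILT_X)) %*%
    rot_axis(c(0, 1, 0), deg2rad(HELIX_TILT_Y))
  placed <- base_frame(
    as.numeric(M %*% (pf$origin + c(0, HELIX_SHIFT_Y, 0))),
    M %*% pf$axes)
  frame_transform(placed, helix_slot_transform(k))
}

#' Ideal A-form RNA duplex
#'
#' Builds a double helix for the given strand-1 sequence and its
#' reverse complement: canonical pair geometry at every slot, standard
#' twist and rise, C3'-endo riboses, phosphates placed by the
#' internal-energy closure search.  Chains are labelled A and B, both
#' written 5' to 3'.
#'
#' @param sequence strand-1 sequence, 5' to 3' (characters ACGU)
#' @param seed unused source of randomness kept for interface symmetry;
#'   the helix is deterministic
#' @return an `rna_structure` with 2 * nchar(sequence) residues
#' @export
ideal_helix <- function(sequence, seed = 1L) {
  s1 <- strsplit(toupper(sequence), "")[[1L]]
  stopifnot(all(s1 %in% c("A", "C", "G", "U")))
  L <- length(s1)
  s2 <- rev(vapply(s1, wc_complement, character(1L)))
  frames1 <- lapply(seq_len(L) - 1L, function(k) {
    helix_slot_frame(k, s1[k + 1L], wc_complement(s1[k + 1L]), 1L)
  })
  # strand-2 residue m (0-based, 5'->3') pairs with strand-1 residue
  # L-1-m, i.e. occupies slot L-1-m
  frames2 <- lapply(seq_len(L) - 1L, function(m) {
    k <- L - 1L - m
    helix_slot_frame(k, s1[k + 1L], wc_complement(s1[k + 1L]), 2L)
  })
  res <- c(
    build_chain(s1, frames1, chain = "A", start_resno = 1L),
    build_chain(s2, frames2, chain = "B", start_resno = 1L)
  )
  rna_structure(res, id = paste0("helix_", sequence))
}

#' Assemble one chain from per-residue frames, then close phosphates
#' @keywords internal
build_chain <- function(types, frames, chain, start_resno = 1L,
                        tables = NULL) {
  L <- length(types)
  res <- vector("list", L)
  for (i in seq_len(L)) {
    xyz <- assemble_residue_xyz(frames[[i]], types[i],
                                ribose_template(types[i]))
    res[[i]] <- base_residue(chain, start_resno + i - 1L, types[i], xyz)
  }
  for (i in seq_len(L - 1L)) {
    ph <- rebuild_phosphate(res[[i]]$xyz, res[[i + 1L]]$xyz, tables)
    res[[i + 1L]]$xyz <- rbind(res[[i + 1L]]$xyz, ph$xyz)
  }
  res
}

#' Tetraloop-like hairpin toy
#'
#' A stem of `n_stem` canonical pairs plus a 4-nt loop placed on a
#' semicircular arc bridging the two strands; the third loop-flanking
#' pair is left to a non-canonical annotation.  The default sequence is
#' the 8-nt GCAA-type tetraloop used throughout the tests.
#'
#' @param sequence full hairpin sequence (length 2 * n_stem + 4)
#' @param n_stem number of canonical stem pairs
#' @param seed kept for interface symmetry; the build is deterministic
#' @return an `rna_structure` (single chain A)
#' @export
hairpin_toy <- function(sequence = "GCGCAAGC", n_stem = 2L, seed = 1L) {
  s <- strsplit(toupper(sequence), "")[[1L]]
  L <- length(s)
  stopifnot(L == 2L * n_stem + 4L)
  frames <- vector("list", L)
  for (k in seq_len(n_stem) - 1L) {
    i5 <- k + 1L            # 5' strand residue (1-based)
    i3 <- L - k             # paired 3' strand residue
    frames[[i5]] <- helix_slot_frame(k, s[i5], s[i3], 1L)
    frames[[i3]] <- helix_slot_frame(k, s[i5], s[i3], 2L)
  }
  # calibrated loop frames (computed once for a 2-pair stem by
  # minimizing phosphate-closure strain subject to steric, stacking and
  # loop-pair constraints), shifted to sit on top of the actual stem
  shift <- helix_slot_transform(n_stem - 2L)
  for (j in 1:4) {
    v <- HAIRPIN_LOOP_FRAMES[j, ]
    ang <- vnorm(v[4:6])
    Rm <- if (ang < 1e-9) diag(3L) else rot_axis(v[4:6] / ang, ang)
    frames[[n_stem + j]] <- frame_transform(base_frame(v[1:3], Rm), shift)
  }
  res <- build_chain(s, frames, chain = "A", start_resno = 1L)
  rna_structure(res, id = paste0("hairpin_", sequence))
}

# origin (x, y, z) and rotation vector (axis * angle, radians) of the
# four loop base frames, in the coordinates of a 2-pair stem
HAIRPIN_LOOP_FRAMES <- matrix(c(
  -8.903442, 3.262963, 2.388824, 0.624646, -0.083498, -1.553335,
  -10.861270, 1.629207, 6.952428, 0.435720, 0.347769, -1.934986,
  -9.495274, 5.782508, 9.205686, 3.474813, -2.334279, 2.225519,
  -5.613830, 8.593422, 9.688557, -1.100917, 1.438060, -0.208247
), 4L, 6L, byrow = TRUE)

#' Axis-angle decomposition of a rotation matrix
#' @keywords internal
rot_axis_angle <- function(R) {
  ca <- (sum(diag(R)) - 1) / 2
  angle <- acos(max(-1, min(1, ca)))
  if (angle < 1e-9) return(list(axis = c(0, 0, 1), angle = 0))
  if (abs(angle - pi) < 1e-6) {
    # axis from the symmetric part
    B <- (R + diag(3L)) / 2
    axis <- sqrt(pmax(diag(B), 0))
    k <- which.max(axis)
    sgn <- sign(B[k, ])
    sgn[sgn == 0] <- 1
    axis <- axis * sgn / sgn[k]
    return(list(axis = axis / vnorm(axis), angle = pi))
  }
  v <- c(R[3L, 2L] - R[2L, 3L], R[1L, 3L] - R[3L, 1L],
         R[2L, 1L] - R[1L, 2L]) / (2 * sin(angle))
  list(axis = v, angle = angle)
}

#' Correlated random perturbation of a structure (decoy generator)
#'
#' Applies an independent small rigid motion to every residue (base +
#' ribose move together) and then re-closes all phosphates, so decoys
#' remain chemically sensible refinement inputs.  The motion amplitude
#' is rescaled once so the all-atom RMSD to the input lands near
#' `sigma`.
#'
#' @param x an `rna_structure`
#' @param sigma target perturbation scale in Angstrom (>= 0)
#' @param seed RNG seed (mandatory; decoys are deterministic per seed)
#' @param tables optional torsion tables for the phosphate closure
#' @return perturbed `rna_structure`
#' @export
perturb_structure <- function(x, sigma, seed, tables = NULL) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(x)
  nres <- length(x$residues)
  rng <- local({ set.seed(as.integer(seed));
    list(tr = matrix(stats::rnorm(3L * nres), nres, 3L),
         ax = matrix(stats::rnorm(3L * nres), nres, 3L),
         an = stats::rnorm(nres)) })
  apply_jitter <- function(scale) {
    res <- x$residues
    for (i in seq_len(nres)) {
      fr <- build_base_frame(res[[i]])
      rot <- rot_axis(unit(rng$ax[i, ]),
                      deg2rad(rng$an[i] * 4 * scale))
      keep <- setdiff(rownames(res[[i]]$xyz), PHOSPHATE_ATOMS)
      m <- res[[i]]$xyz[keep, , drop = FALSE]
      m <- sweep(m, 2L, fr$origin)
      m <- m %*% t(rot)
      m <- sweep(m, 2L, fr$origin + rng$tr[i, ] * scale / sqrt(3), "+")
      res[[i]]$xyz <- m
      res[[i]]$cache <- NULL
    }
    # re-close phosphates along each chain
    ch <- vapply(res, function(r) r$chain, character(1L))
    for (i in seq_len(nres - 1L)) {
      if (ch[i] == ch[i + 1L]) {
        ph <- rebuild_phosphate(res[[i]]$xyz, res[[i + 1L]]$xyz, tables)
        res[[i + 1L]]$xyz <- rbind(res[[i + 1L]]$xyz, ph$xyz)
        res[[i + 1L]]$cache <- NULL
      }
    }
    rna_structure(res, id = paste0(x$id, "_decoy", seed))
  }
  d1 <- apply_jitter(sigma)
  r1 <- structure_rmsd(x, d1)
  if (r1 < 1e-9) return(d1)
  apply_jitter(sigma * sigma / r1)
}

#' Planted-mode synthetic pair library
#'
#' Draws pair observations from a mixture of rigid-body modes with
#' known weights and spreads, for parameter-recovery tests of the
#' kernel density and table construction.
#'
#' @param modes list of modes, each a list with `frame_j` (a
#'   `base_frame` giving the partner placement relative to an identity
#'   frame at the origin), `weight` and `spread` (Angstrom jitter scale)
#' @param n number of observations
#' @param seed RNG seed
#' @param types base types of the pair (default GC)
#' @param sep separation class recorded on each observation
#' @return a `pair_library` with a single group
#' @export
synthetic_pair_library <- function(modes, n, seed, types = c("G", "C"),
                                   sep = "2+") {
  w <- vapply(modes, function(m) m$weight, numeric(1L))
  stopifnot(abs(sum(w) - 1) < 1e-8)
  set.seed(as.integer(seed))
  fi <- base_frame(c(0, 0, 0), diag(3L))
  obs <- vector("list", n)
  if (n > 0L) {
    pick <- sample.int(length(modes), n, replace = TRUE, prob = w)
    for (i in seq_len(n)) {
      m <- modes[[pick[i]]]
      rot <- rot_axis(unit(stats::rnorm(3L)),
                      stats::rnorm(1L) * m$spread * 0.5)
      fj <- base_frame(m$frame_j$origin + stats::rnorm(3L) * m$spread,
                       rot %*% m$frame_j$axes)
      orient <- relative_orientation(fi, fj)
      d16 <- pair_configuration(fi, fj, types, sep)$d16
      obs[[i]] <- list(
        types = types, sep = sep, rel = 99L, source = "synthetic",
        mode = pick[i], orient = orient, d16 = d16)
    }
  }
  new_pair_library(obs)
}

#' Synthetic stand-in for the quantum pair-energy table
#'
#' Assigns an interaction energy to every orientation cluster center by
#' a stated analytic rule.  The default "contact" rule deepens the
#' energy as the two bases' pseudo-atoms approach contact, so
#' hydrogen-bonded and stacked centers span roughly -30 to -10
#' kcal/mol while distant centers approach zero, mimicking the scale
#' of ab initio pair energies without running any quantum chemistry.
#'
#' @param clusters an `orientation_clusters`
#' @param rule "contact" (depth grows with pseudo-atom proximity) or
#'   "zero" (all zero, reducing every reweighting factor to 1/f)
#' @return a `qm_table` with one energy (kcal/mol) per center
#' @export
toy_qm_table <- function(clusters, rule = c("contact", "zero")) {
  rule <- match.arg(rule)
  energies <- switch(rule,
    zero = rep(0, nrow(clusters$centers)),
    contact = {
      mind <- apply(clusters$centers, 1L, min)
      -30 * pmin(1, pmax(0, (6.0 - mind) / 3.5))
    })
  structure(list(types = clusters$types, rule = rule,
                 energies = energies, n = length(energies)),
            class = "qm_table")
}

#' Deterministic fixture corpus: five duplexes and two hairpins
#'
#' The sequences are chosen so every unordered base-pair type occurs
#' at several separations, populating all mandatory statistics
#' classes.
#'
#' @param seed fixture seed (forwarded; the corpus is deterministic)
#' @return list of `rna_structure` objects
#' @export
fixture_corpus <- function(seed = 1L) {
  c(lapply(c("GCGCGCGCGC", "AUAUAUAUAU", "GAGAGAGAGA", "GUGUGUGUGU",
             "GGAAUUCCGG"),
           ideal_helix, seed = seed),
    list(hairpin_toy("GCGCAAGC", seed = seed),
         hairpin_toy("AUGCAAAU", seed = seed)))
}
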