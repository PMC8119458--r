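#' Minimum-approach radii from corpus statistics
#'
#' The clash radius r0 of an atom-type pair is the 5th percentile of
#' the observed short-range (< 5 A) distances between atoms of those
#' types, excluding pairs within three covalent bonds.  For pairs
#' involving a base atom (SP2 partner) r0 is additionally resolved on a
#' 1 A Cartesian grid in the base-local frame, falling back to the
#' isotropic value in sparse cells.
#'
#' @name clash-table
NULL

CLASH_COLLECT_RANGE <- 5
CLASH_MIN_OBS <- 20
CLASH_CELL_MIN_OBS <- 4
CLASH_FALLBACK_R0 <- 2.6

# hard-sphere ceilings on the percentile estimator, per element pair.
# On a small corpus the short-distance tail is under-sampled and the
# 5th percentile lands far above any physical contact limit; the
# ceiling keeps sparse-data radii at hydrogen-bond-aware hard-core
# values (heavy-atom pairs, no explicit hydrogens).
CLASH_R0_CAP <- c("C|C" = 3.10, "C|N" = 3.00, "C|O" = 2.90,
                  "N|N" = 2.75, "N|O" = 2.65, "O|O" = 2.60,
                  "C|P" = 3.30, "N|P" = 3.20, "O|P" = 2.90,
                  "P|P" = 3.50)

r0_cap <- function(c1, c2) {
  e <- sort(c(substr(c1, 1L, 1L), substr(c2, 1L, 1L)))
  CLASH_R0_CAP[[paste0(e[1L], "|", e[2L])]] %||% 3.3
}

#' Covalent bond list of a residue type (atom-name pairs)
#' @keywords internal
residue_bonds <- function(type) {
  key <- paste0("bonds_", type)
  cached <- geometry_cache[[key]]
  if (!is.null(cached)) return(cached)
  sugar <- list(c("C1'", "C2'"), c("C2'", "C3'"), c("C3'", "C4'"),
                c("C4'", "O4'"), c("O4'", "C1'"), c("C2'", "O2'"),
                c("C3'", "O3'"), c("C4'", "C5'"), c("C5'", "O5'"),
                c("O5'", "P"), c("P", "OP1"), c("P", "OP2"))
  ring <- if (is_purine(type)) {
    list(c("C1'", "N9"), c("N9", "C4"), c("C4", "C5"), c("C5", "N7"),
         c("N7", "C8"), c("C8", "N9"), c("C4", "N3"), c("N3", "C2"),
         c("C2", "N1"), c("N1", "C6"), c("C6", "C5"))
  } else {
    list(c("C1'", "N1"), c("N1", "C2"), c("C2", "N3"), c("N3", "C4"),
         c("C4", "C5"), c("C5", "C6"), c("C6", "N1"), c("C2", "O2"))
  }
  exo <- switch(type,
    A = list(c("C6", "N6")),
    G = list(c("C6", "O6"), c("C2", "N2")),
    C = list(c("C4", "N4")),
    U = list(c("C4", "O4")))
  out <- c(sugar, ring, exo)
  geometry_cache[[key]] <- out
  out
}

#' Atom pairs of one or two residues within `depth` covalent bonds
#'
#' For `junction = TRUE` the atoms of residue j are prefixed "j:" and
#' the inter-residue O3'-P bond is included.
#' @keywords internal
bonded_pairs <- function(type_i, type_j = NULL, depth = 3L) {
  key <- paste0("excl_", type_i, "_", type_j %||% "", "_", depth)
  cached <- geometry_cache[[key]]
  if (!is.null(cached)) return(cached)
  edges <- lapply(residue_bonds(type_i), function(b) paste0("i:", b))
  if (!is.null(type_j)) {
    edges <- c(edges,
               lapply(residue_bonds(type_j), function(b) paste0("j:", b)),
               list(c("i:O3'", "j:P")))
  }
  nodes <- unique(unlist(edges))
  adj <- lapply(stats::setNames(nodes, nodes), function(x) character(0L))
  for (e in edges) {
    adj[[e[1L]]] <- c(adj[[e[1L]]], e[2L])
    adj[[e[2L]]] <- c(adj[[e[2L]]], e[1L])
  }
  out <- new.env(parent = emptyenv())
  for (start in nodes) {
    seen <- stats::setNames(0L, start)
    frontier <- start
    for (d in seq_len(depth)) {
      nxt <- setdiff(unique(unlist(adj[frontier])), names(seen))
      if (!length(nxt)) break
      seen <- c(seen, stats::setNames(rep(d, length(nxt)), nxt))
      frontier <- nxt
    }
    for (other in names(seen)) {
      if (other != start) out[[paste0(start, "|", other)]] <- TRUE
    }
  }
  geometry_cache[[key]] <- out
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clash atom class of an atom name
#'
#' Backbone atoms keep their specific name (OP1/OP2 merged to OP) so
#' the statistical radii reflect each atom's own contact envelope;
#' base atoms are classed by element, with orientation-resolved radii
#' layered on top.
#' @keywords internal
atom_class <- function(name, is_base) {
  if (is_base) paste0(substr(name, 1L, 1L), "b")
  else if (name %in% c("OP1", "OP2")) "OP"
  else name
}

clash_key <- function(c1, c2) paste0(sort(c(c1, c2)), collapse = "|")

#' Estimate the clash radii table from a corpus
#'
#' @param corpus list of `rna_structure` objects
#' @param fallback radius used for atom-type pairs with fewer than 20
#'   observations (Angstrom)
#' @return a `clash_table` with isotropic radii per atom-class pair and
#'   orientation-resolved radii for base-atom partners
#' @export
estimate_r0 <- function(corpus, fallback = CLASH_FALLBACK_R0) {
  samples <- new.env(parent = emptyenv())
  cells <- new.env(parent = emptyenv())
  push <- function(env, key, val) env[[key]] <- c(env[[key]], val)
  for (s in corpus) {
    res <- s$residues
    n <- length(res)
    frames <- structure_frames(s)
    for (i in seq_len(n)) {
      for (j in i:n) {
        same <- i == j
        junction <- !same && is_chain_neighbour(res[[i]], res[[j]]) &&
          abs(res[[i]]$resno - res[[j]]$resno) == 1L
        excl <- if (same) bonded_pairs(res[[i]]$type)
                else if (junction) bonded_pairs(res[[i]]$type,
                                                res[[j]]$type)
                else NULL
        A <- res[[i]]$xyz; B <- res[[j]]$xyz
        D <- cross_dist(A, B)
        hits <- which(D < CLASH_COLLECT_RANGE & D > 0, arr.ind = TRUE)
        for (h in seq_len(nrow(hits))) {
          ai <- rownames(A)[hits[h, 1L]]
          aj <- rownames(B)[hits[h, 2L]]
          if (same && hits[h, 2L] <= hits[h, 1L]) next
          if (!is.null(excl)) {
            k1 <- if (same) paste0("i:", ai, "|i:", aj)
                  else paste0("i:", ai, "|j:", aj)
            if (isTRUE(excl[[k1]])) next
          }
          bi <- ai %in% base_atom_names(res[[i]]$type)
          bj <- aj %in% base_atom_names(res[[j]]$type)
          ci <- atom_class(ai, bi)
          cj <- atom_class(aj, bj)
          d <- D[hits[h, 1L], hits[h, 2L]]
          push(samples, clash_key(ci, cj), d)
          # orientation-resolved sample for each base-atom partner
          if (bi) {
            loc <- as.numeric(t(frames[[i]]$axes) %*%
                                (B[aj, ] - frames[[i]]$origin))
            push(cells, paste0(cj, "@", res[[i]]$type, ":", ai, "|",
                               paste(floor(loc), collapse = ",")), d)
          }
          if (bj) {
            loc <- as.numeric(t(frames[[j]]$axes) %*%
                                (A[ai, ] - frames[[j]]$origin))
            push(cells, paste0(ci, "@", res[[j]]$type, ":", aj, "|",
                               paste(floor(loc), collapse = ",")), d)
          }
        }
      }
    }
  }
  iso <- new.env(parent = emptyenv())
  for (k in ls(samples)) {
    v <- samples[[k]]
    cls <- strsplit(k, "|", fixed = TRUE)[[1L]]
    iso[[k]] <- if (length(v) >= CLASH_MIN_OBS) {
      # strict lower bound: ties at the percentile itself must not clash
      min(as.numeric(stats::quantile(v, 0.05, type = 1L)) - 1e-6,
          r0_cap(cls[1L], cls[2L]))
    } else min(fallback, r0_cap(cls[1L], cls[2L]))
  }
  oriented <- new.env(parent = emptyenv())
  for (k in ls(cells)) {
    v <- cells[[k]]
    if (length(v) >= CLASH_CELL_MIN_OBS) {
      partner <- sub("@.*", "", k)
      batom <- sub(".*@[ACGU]:([A-Z0-9']+)\\|.*", "\\1", k)
      oriented[[k]] <- min(
        as.numeric(stats::quantile(v, 0.05, type = 1L)) - 1e-6,
        r0_cap(partner, batom))
    }
  }
  structure(list(iso = iso, oriented = oriented, fallback = fallback),
            class = "clash_table")
}

#' Look up r0 for an atom pair (isotropic path)
#' @keywords internal
r0_lookup <- function(table, c1, c2) {
  table$iso[[clash_key(c1, c2)]] %||% table$fallback
}

#' Orientation-resolved r0 for a partner atom near a base atom
#' @keywords internal
r0_lookup_oriented <- function(table, partner_class, base_type,
                               base_atom, loc) {
  key <- paste0(partner_class, "@", base_type, ":", base_atom, "|",
                paste(floor(loc), collapse = ","))
  table$oriented[[key]] %||%
    r0_lookup(table, partner_class,
              atom_class(base_atom, TRUE))
}
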