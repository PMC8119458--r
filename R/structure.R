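#' RNA structure container
#'
#' An `rna_structure` is an ordered list of `base_residue` records
#' (strictly increasing residue indices within a chain) plus light
#' metadata.  It is the common currency of the statistics collectors,
#' the scoring functions and the sampler.
#'
#' @name rna-structure
NULL

#' Create an RNA structure from a list of residues
#' @param residues list of `base_residue` objects
#' @param id source identifier (file name or fixture name)
#' @export
rna_structure <- function(residues, id = "structure") {
  stopifnot(length(residues) >= 1L)
  ch <- vapply(residues, function(r) r$chain, character(1L))
  no <- vapply(residues, function(r) r$resno, integer(1L))
  for (cc in unique(ch)) {
    idx <- no[ch == cc]
    if (any(diff(idx) <= 0)) {
      stop("residue indices not strictly increasing in chain ", cc)
    }
  }
  structure(list(residues = residues, id = id), class = "rna_structure")
}

#' @export
length.rna_structure <- function(x) length(x$residues)

#' @export
print.rna_structure <- function(x, ...) {
  cat("rna_structure '", x$id, "': ", length(x$residues), " residues (",
      paste(structure_sequence(x), collapse = ""), ")\n", sep = "")
  invisible(x)
}

#' Base sequence of a structure
#' @param x an `rna_structure`
#' @export
structure_sequence <- function(x) {
  vapply(x$residues, function(r) r$type, character(1L))
}

#' All atom coordinates of a structure
#'
#' @param x an `rna_structure`
#' @param atoms optional character vector restricting the atom names
#' @return N x 3 matrix with rownames "resindex:atom"
#' @export
structure_coords <- function(x, atoms = NULL) {
  out <- lapply(seq_along(x$residues), function(i) {
    m <- x$residues[[i]]$xyz
    if (!is.null(atoms)) m <- m[rownames(m) %in% atoms, , drop = FALSE]
    if (nrow(m)) rownames(m) <- paste0(i, ":", rownames(m))
    m
  })
  do.call(rbind, out)
}

#' Are two residues sequence neighbours in the same chain?
#' @keywords internal
is_chain_neighbour <- function(a, b) {
  a$chain == b$chain && abs(a$resno - b$resno) == 1L
}

#' Separation class of a residue pair
#'
#' Intra-chain index difference 1 or 2; everything farther, and every
#' inter-chain pair, is non-local ("2+").
#' @keywords internal
separation_class <- function(a, b) {
  if (a$chain != b$chain) return("2+")
  d <- abs(a$resno - b$resno)
  if (d == 1L) "1" else if (d == 2L) "2" else "2+"
}

#' Chain-break rule: neighbours farther than this between P and O3' are
#' treated as disconnected
#' @keywords internal
CHAIN_BREAK_P_O3 <- 2.5

#' All-atom RMSD between two structures with identical atom sets
#' @param a,b `rna_structure` objects over the same residues
#' @param superpose superpose first (default) or compare in place
#' @export
structure_rmsd <- function(a, b, superpose = TRUE) {
  ca <- structure_coords(a)
  cb <- structure_coords(b)
  common <- intersect(rownames(ca), rownames(cb))
  ca <- ca[common, , drop = FALSE]
  cb <- cb[common, , drop = FALSE]
  if (superpose) {
    superpose_rmsd(ca, cb)
  } else {
    sqrt(mean(rowSums((ca - cb)^2)))
  }
}

#' Base frames of every residue
#' @keywords internal
structure_frames <- function(x) lapply(x$residues, build_base_frame)

#' Assemble a residue's atoms from a frame, a local ribose and a type
#'
#' Base atoms come from the idealized base template; ribose atoms from a
#' rotamer conformer expressed in the base-local frame.  Phosphate atoms
#' (P, OP1, OP2, O5'), which belong to the 5' side of the residue, are
#' appended separately once the junction torsions are known.
#'
#' @keywords internal
assemble_residue_xyz <- function(frame, type, ribose_local) {
  base <- base_template(type)
  loc <- rbind(base, ribose_local[setdiff(rownames(ribose_local),
                                          rownames(base)), , drop = FALSE])
  g <- sweep(loc %*% t(frame$axes), 2L, frame$origin, "+")
  rownames(g) <- rownames(loc)
  colnames(g) <- c("x", "y", "z")
  g
}

#' Ribose atoms of a residue expressed in its own base frame
#' @keywords internal
residue_ribose_local <- function(res, frame = NULL) {
  if (is.null(frame)) frame <- build_base_frame(res)
  nm <- RIBOSE_ATOMS[RIBOSE_ATOMS %in% rownames(res$xyz)]
  g <- res$xyz[nm, , drop = FALSE]
  loc <- sweep(g, 2L, frame$origin) %*% frame$axes
  rownames(loc) <- nm
  loc
}

RIBOSE_ATOMS <- c("C1'", "C2'", "C3'", "C4'", "O4'", "O2'", "O3'", "C5'")
PHOSPHATE_ATOMS <- c("P", "OP1", "OP2", "O5'")
BACKBONE_OXYGENS <- c("OP1", "OP2", "O2'", "O3'", "O4'", "O5'")
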