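#' Reading and writing structures and annotations
#'
#' PDB input/output (through bio3d) with the normalizations RNA work
#' needs: legacy primed-star atom names, altloc resolution, non-RNA
#' entities skipped.  The pairing annotation is a small text format:
#' line 1 the sequence, line 2 a dot-bracket string (pseudoknot
#' brackets `[]` and `{}` supported), further lines `i j NWC` for
#' non-Watson-Crick pairs (1-based indices).
#'
#' @name io
NULL

RNA_RES_NAMES <- c("A", "C", "G", "U", "RA", "RC", "RG", "RU",
                   "ADE", "CYT", "GUA", "URA", "URI")

normalize_atom_name <- function(a) {
  a <- gsub("*", "'", a, fixed = TRUE)
  a
}

#' Read an RNA structure from a PDB file
#'
#' @param path PDB file
#' @param model model number to read (default 1)
#' @return an `rna_structure`
#' @export
read_rna <- function(path, model = 1L) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at$elety <- normalize_atom_name(at$elety)
  resmap <- c(A = "A", RA = "A", ADE = "A", C = "C", RC = "C",
              CYT = "C", G = "G", RG = "G", GUA = "G", U = "U",
              RU = "U", URA = "U", URI = "U")
  keep <- at$resid %in% names(resmap)
  if (!any(keep)) stop("no RNA residues in ", path)
  n_skipped <- length(unique(paste(at$chain[!keep], at$resno[!keep])))
  if (n_skipped > 0L) {
    message("skipping ", n_skipped, " non-RNA residues in ", path)
  }
  at <- at[keep, , drop = FALSE]
  if (any(nzchar(at$insert) & !is.na(at$insert))) {
    stop("insertion codes are not supported; renumber the input first")
  }
  # altloc: keep blank or 'A'
  alt_ok <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[alt_ok, , drop = FALSE]
  key <- paste(at$chain, at$resno)
  residues <- list()
  for (k in unique(key)) {
    sel <- at[key == k, , drop = FALSE]
    sel <- sel[!duplicated(sel$elety), , drop = FALSE]
    xyz <- cbind(sel$x, sel$y, sel$z)
    rownames(xyz) <- sel$elety
    colnames(xyz) <- c("x", "y", "z")
    type <- resmap[[sel$resid[1L]]]
    residues[[length(residues) + 1L]] <-
      base_residue(sel$chain[1L], sel$resno[1L], type, xyz)
  }
  # order by chain then residue number
  ord <- order(vapply(residues, function(r) r$chain, character(1L)),
               vapply(residues, function(r) r$resno, integer(1L)))
  rna_structure(residues[ord], id = basename(path))
}

#' Write an RNA structure (or several models) to a PDB file
#'
#' Standard ATOM records with occupancy 1.00 and the element column
#' filled; multiple structures produce MODEL/ENDMDL blocks.
#'
#' @param x an `rna_structure` or a list of them (models)
#' @param path output file
#' @export
write_rna <- function(x, path) {
  models <- if (inherits(x, "rna_structure")) list(x) else x
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1L
  for (m in seq_along(models)) {
    if (multi) writeLines(sprintf("MODEL %8d", m), con)
    serial <- 0L
    for (res in models[[m]]$residues) {
      for (a in rownames(res$xyz)) {
        serial <- serial + 1L
        el <- substr(a, 1L, 1L)
        writeLines(sprintf(
          "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, a, res$type, res$chain, res$resno,
          res$xyz[a, 1L], res$xyz[a, 2L], res$xyz[a, 3L], 1, 0, el), con)
      }
    }
    writeLines(if (multi) "ENDMDL" else "END", con)
  }
  invisible(NULL)
}

BRACKET_PAIRS <- list(c("(", ")"), c("[", "]"), c("{", "}"))

#' Parse a dot-bracket string into a pair list
#' @keywords internal
parse_dotbracket <- function(db) {
  ch <- strsplit(db, "")[[1L]]
  pairs <- NULL
  for (bp in BRACKET_PAIRS) {
    stack <- integer(0L)
    for (i in seq_along(ch)) {
      if (ch[i] == bp[1L]) stack <- c(stack, i)
      else if (ch[i] == bp[2L]) {
        if (!length(stack)) stop("unbalanced '", bp[2L],
                                 "' at position ", i)
        pairs <- rbind(pairs, c(stack[length(stack)], i))
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack)) stop("unbalanced '", bp[1L], "' (",
                            length(stack), " unclosed)")
  }
  bad <- !ch %in% c(".", unlist(BRACKET_PAIRS))
  if (any(bad)) stop("invalid dot-bracket characters: ",
                     paste(unique(ch[bad]), collapse = " "))
  pairs
}

#' Read a pairing annotation file
#'
#' @param path text file: sequence line, dot-bracket line, optional
#'   `i j NWC` lines (1-based)
#' @return a `pairing_annotation` with `sequence`, `wc` (2-column
#'   matrix) and `nwc`
#' @export
read_pairing <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  if (length(ln) < 2L) stop("pairing file needs a sequence line and a",
                            " dot-bracket line")
  pairing_annotation(trimws(ln[1L]), trimws(ln[2L]),
                     if (length(ln) > 2L) ln[-(1:2)] else character(0L))
}

#' Construct and validate a pairing annotation
#'
#' @param sequence RNA sequence (ACGU)
#' @param dotbracket dot-bracket string of the same length
#' @param nwc_lines character vector of "i j NWC" lines, or a 2-column
#'   matrix of indices
#' @export
pairing_annotation <- function(sequence, dotbracket,
                               nwc_lines = character(0L)) {
  seqc <- strsplit(toupper(sequence), "")[[1L]]
  if (!all(seqc %in% c("A", "C", "G", "U"))) {
    stop("sequence contains non-ACGU characters")
  }
  if (nchar(dotbracket) != length(seqc)) {
    stop("sequence and dot-bracket lengths differ")
  }
  wc <- parse_dotbracket(dotbracket)
  nwc <- if (is.matrix(nwc_lines)) nwc_lines else {
    out <- NULL
    for (l in nwc_lines) {
      f <- strsplit(trimws(l), "\\s+")[[1L]]
      if (length(f) < 2L) stop("malformed pair line: ", l)
      out <- rbind(out, as.integer(f[1:2]))
    }
    out
  }
  n <- length(seqc)
  for (m in list(wc, nwc)) {
    if (!is.null(m) && (any(m < 1L) || any(m > n))) {
      stop("pair index out of range 1..", n)
    }
  }
  if (!is.null(wc) && anyDuplicated(as.vector(wc))) {
    stop("duplicate Watson-Crick partner")
  }
  structure(list(sequence = seqc, wc = wc, nwc = nwc),
            class = "pairing_annotation")
}

#' Write a table bundle to a versioned archive
#' @param tables a `refine_tables`
#' @param path output file (RDS serialization)
#' @export
write_table_archive <- function(tables, path) {
  stopifnot(inherits(tables, "refine_tables"))
  saveRDS(tables, path)
  invisible(path)
}

#' Read a table bundle archive
#' @param path archive written by [write_table_archive()]
#' @export
read_table_archive <- function(path) {
  tables <- readRDS(path)
  if (!inherits(tables, "refine_tables")) stop("not a table archive")
  if (!identical(tables$version, TABLE_ARCHIVE_VERSION)) {
    stop("table archive version ", tables$version,
         " does not match supported version ", TABLE_ARCHIVE_VERSION)
  }
  tables
}
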