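#' Nucleobase-centric fold tree
#'
#' Conformations are represented by a spanning tree over residues:
#' each node carries a base frame and a ribose rotamer, each edge a
#' rigid transform between parent and child frames, typed by its
#' pairing context.  Node moves perturb one base locally; edge moves
#' transform a whole subtree rigidly, preserving all internal
#' geometry.  Phosphates bridging residues whose relative placement
#' changed are rebuilt by the hierarchical epsilon-zeta search.
#'
#' @name nutree
NULL

EDGE_TYPES <- c("wc-pair", "nwc-pair", "wc-nb-53", "wc-nb-35",
                "nwc-nb", "loop-nb-53", "loop-nb-35", "jump")

edge_priority <- c("wc-pair" = 1, "nwc-pair" = 2, "wc-nb-53" = 3,
                   "wc-nb-35" = 3, "nwc-nb" = 4, "loop-nb-53" = 5,
                   "loop-nb-35" = 5, "jump" = 6)

#' Step-count class of an edge type (wc / nwc / other)
#' @keywords internal
edge_step_class <- function(type) {
  if (type %in% c("wc-pair", "wc-nb-53", "wc-nb-35")) "wc"
  else if (type %in% c("nwc-pair", "nwc-nb")) "nwc"
  else "other"
}

#' Build the fold tree for a sequence and pairing annotation
#'
#' Candidate edges are typed from the annotation (canonical-pair
#' edges, non-canonical-pair edges, and sequence-neighbour edges whose
#' class reflects the pairing context of both ends); the spanning tree
#' keeps the highest-priority edges (pairs before helix neighbours
#' before loop neighbours), surplus connections remaining as scored
#' constraints only.  The root is the first residue of the longest
#' canonical helix.  Nested and pseudoknotted pairings are both
#' accepted.
#'
#' @param structure an `rna_structure` providing initial coordinates
#' @param pairing a `pairing_annotation` of matching length
#' @return a `nutree` state (environment)
#' @export
build_nutree <- function(structure, pairing) {
  res <- structure$residues
  n <- length(res)
  if (n < 2L) stop("need at least 2 residues")
  if (length(pairing$sequence) != n) {
    stop("pairing annotation length ", length(pairing$sequence),
         " does not match structure length ", n)
  }
  types <- structure_sequence(structure)
  if (!identical(types, pairing$sequence)) {
    stop("pairing sequence does not match structure sequence")
  }
  wc_partner <- rep(NA_integer_, n)
  if (!is.null(pairing$wc)) {
    for (k in seq_len(nrow(pairing$wc))) {
      i <- pairing$wc[k, 1L]; j <- pairing$wc[k, 2L]
      if (!is.na(wc_partner[i]) || !is.na(wc_partner[j])) {
        stop("conflicting pairing: residue in more than one WC pair")
      }
      wc_partner[i] <- j; wc_partner[j] <- i
    }
  }
  nwc_partner <- rep(NA_integer_, n)
  if (!is.null(pairing$nwc)) {
    for (k in seq_len(nrow(pairing$nwc))) {
      i <- pairing$nwc[k, 1L]; j <- pairing$nwc[k, 2L]
      nwc_partner[i] <- j; nwc_partner[j] <- i
    }
  }
  paired <- !is.na(wc_partner) | !is.na(nwc_partner)
  chains <- vapply(res, function(r) r$chain, character(1L))
  # candidate edges in priority order
  cand <- list()
  add <- function(i, j, type) {
    cand[[length(cand) + 1L]] <<- list(i = i, j = j, type = type)
  }
  if (!is.null(pairing$wc)) {
    for (k in seq_len(nrow(pairing$wc))) {
      add(pairing$wc[k, 1L], pairing$wc[k, 2L], "wc-pair")
    }
  }
  if (!is.null(pairing$nwc)) {
    for (k in seq_len(nrow(pairing$nwc))) {
      add(pairing$nwc[k, 1L], pairing$nwc[k, 2L], "nwc-pair")
    }
  }
  for (i in seq_len(n - 1L)) {
    j <- i + 1L
    if (chains[i] != chains[j]) next
    type <- if (!is.na(wc_partner[i]) && !is.na(wc_partner[j]) &&
                wc_partner[i] == wc_partner[j] + 1L) {
      "wc-nb-53"
    } else if (paired[i] && paired[j]) {
      "nwc-nb"
    } else {
      "loop-nb-53"
    }
    add(i, j, type)
  }
  # jump edges between consecutive chains
  for (cc in unique(chains)[-1L]) {
    add(which(chains == unique(chains)[1L])[1L], which(chains == cc)[1L],
        "jump")
  }
  ord <- order(vapply(cand, function(e) edge_priority[[e$type]],
                      numeric(1L)))
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  tree_edges <- list(); constraints <- list()
  for (e in cand[ord]) {
    ri <- find(e$i); rj <- find(e$j)
    if (ri != rj) {
      comp[ri] <- rj
      tree_edges[[length(tree_edges) + 1L]] <- e
    } else {
      constraints[[length(constraints) + 1L]] <- e
    }
  }
  if (length(tree_edges) != n - 1L) stop("pairing yields a disconnected",
                                         " tree")
  # root: first residue of the longest WC helix
  root <- 1L
  best_run <- 0L; run <- 0L
  for (i in seq_len(n)) {
    if (!is.na(wc_partner[i])) run <- run + 1L else run <- 0L
    if (run > best_run) { best_run <- run; root <- i - run + 1L }
  }
  # orient edges away from the root
  adj <- vector("list", n)
  for (k in seq_along(tree_edges)) {
    e <- tree_edges[[k]]
    adj[[e$i]] <- c(adj[[e$i]], k)
    adj[[e$j]] <- c(adj[[e$j]], k)
  }
  parent <- rep(NA_integer_, n)
  children <- vector("list", n)
  edge_of <- rep(NA_integer_, n)   # edge index leading into node
  edge_type <- rep(NA_character_, n)
  visited <- rep(FALSE, n)
  queue <- root; visited[root] <- TRUE
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    for (k in adj[[u]]) {
      e <- tree_edges[[k]]
      v <- if (e$i == u) e$j else e$i
      if (visited[v]) next
      visited[v] <- TRUE
      parent[v] <- u
      children[[u]] <- c(children[[u]], v)
      edge_of[v] <- k
      ty <- e$type
      # direction-sensitive neighbour types
      if (ty %in% c("wc-nb-53", "loop-nb-53") && e$i != u) {
        ty <- sub("-53", "-35", ty)
      }
      edge_type[v] <- ty
      queue <- c(queue, v)
    }
  }
  st <- new.env(parent = emptyenv())
  st$n <- n
  st$types <- types
  st$chains <- chains
  st$root <- root
  st$parent <- parent
  st$children <- children
  st$edge_type <- edge_type
  st$constraints <- constraints
  st$wc_partner <- wc_partner
  st$nwc_partner <- nwc_partner
  st$res <- res
  st$frames <- structure_frames(structure)
  st$edge_rt <- vector("list", n)
  for (v in seq_len(n)) {
    if (!is.na(parent[v])) {
      st$edge_rt[[v]] <- frame_relative_rt(st$frames[[parent[v]]],
                                           st$frames[[v]])
    }
  }
  class(st) <- "nutree"
  st
}

#' @export
print.nutree <- function(x, ...) {
  cat("nutree:", x$n, "nodes, root", x$root, "\n")
  for (v in seq_len(x$n)) {
    if (!is.na(x$parent[v])) {
      cat(sprintf("  %d -> %d  %s\n", x$parent[v], v, x$edge_type[v]))
    }
  }
  invisible(x)
}

#' All nodes in the subtree rooted at v (inclusive)
#' @keywords internal
subtree_nodes <- function(st, v) {
  out <- v; queue <- v
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    ch <- st$children[[u]]
    out <- c(out, ch)
    queue <- c(queue, ch)
  }
  sort(out)
}

#' Structure snapshot of the current tree state
#' @param st a `nutree`
#' @param id identifier for the snapshot
#' @export
nutree_structure <- function(st, id = "nutree_state") {
  rna_structure(st$res, id = id)
}

#' Step-count of the annealing schedule for this tree
#'
#' 400 per canonical (pair or helix-neighbour) edge, 2000 per
#' non-canonical edge, 4000 per other edge.
#' @param st a `nutree`
#' @export
nutree_n_step <- function(st) {
  cls <- vapply(which(!is.na(st$parent)), function(v) {
    edge_step_class(st$edge_type[v])
  }, character(1L))
  sum(c(wc = 400, nwc = 2000, other = 4000)[cls])
}
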