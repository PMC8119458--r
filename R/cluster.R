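#' Orientation clustering under the distance-matrix metric
#'
#' k-medoid clustering of pair configurations with the DDM
#' pseudo-metric: used for the representative centers that anchor the
#' quantum-energy reweighting and, in two levels, for the edge move
#' sets.
#'
#' @name orientation-clustering
NULL

ddm_matrix <- function(M) {
  n <- nrow(M)
  G <- M %*% t(M)
  d2 <- outer(diag(G), diag(G), "+") - 2 * G
  sqrt(pmax(d2, 0) / 16)
}

#' k-medoid clustering of a configuration set
#'
#' Minimizes the root-mean-square DDM from every observation to its
#' nearest center; the objective is non-increasing over iterations and
#' the result is deterministic for a fixed seed.
#'
#' @param M N x 16 matrix of flattened pseudo-atom cross-distance
#'   matrices
#' @param k number of clusters
#' @param seed RNG seed for the initial medoids
#' @param maxit iteration cap
#' @return list with `medoid_idx`, `centers` (k x 16), `assign`,
#'   `objective` (RMS DDM) and the per-iteration objective trace
#' @export
kmedoids_ddm <- function(M, k, seed = 1L, maxit = 60L) {
  n <- nrow(M)
  if (n < k) stop("fewer observations (", n, ") than clusters (", k,
                  "); use a smaller k")
  set.seed(as.integer(seed))
  D <- ddm_matrix(M)
  med <- sample.int(n, k)
  obj_trace <- numeric(0L)
  assign <- NULL
  for (it in seq_len(maxit)) {
    A <- D[, med, drop = FALSE]
    assign <- max.col(-A, ties.method = "first")
    obj <- sqrt(mean(A[cbind(seq_len(n), assign)]^2))
    obj_trace <- c(obj_trace, obj)
    new_med <- med
    for (c in seq_len(k)) {
      members <- which(assign == c)
      if (!length(members)) next
      sub <- D[members, members, drop = FALSE]
      new_med[c] <- members[which.min(colSums(sub^2))]
    }
    if (all(new_med == med)) break
    med <- new_med
  }
  A <- D[, med, drop = FALSE]
  assign <- max.col(-A, ties.method = "first")
  list(medoid_idx = med, centers = M[med, , drop = FALSE],
       assign = assign,
       objective = sqrt(mean(A[cbind(seq_len(n), assign)]^2)),
       trace = obj_trace)
}

#' Orientation cluster centers for one base-pair type
#'
#' @param library a `pair_library`
#' @param types base-type pair, e.g. c("G", "C")
#' @param sep separation class clustered (non-local "2+" by default,
#'   the class whose density is QM-reweighted)
#' @param k number of centers (80 in the full-scale protocol;
#'   configurable for desk-scale corpora)
#' @param seed RNG seed
#' @return an `orientation_clusters` object with `centers`, `assign`,
#'   `objective` and the observation matrix used
#' @export
cluster_orientations <- function(library, types, sep = "2+", k = 80L,
                                 seed = 1L) {
  grp <- pair_group(library, types, sep)
  if (is.null(grp)) stop("no observations for ",
                         canonical_pair(types[1L], types[2L]), " sep ", sep)
  km <- kmedoids_ddm(grp$d16, k, seed)
  structure(list(types = sort(types), sep = sep, k = k,
                 centers = km$centers, assign = km$assign,
                 medoid_idx = km$medoid_idx, objective = km$objective,
                 trace = km$trace, d16 = grp$d16),
            class = "orientation_clusters")
}

#' Nearest cluster center of configurations
#' @param clusters an `orientation_clusters`
#' @param d16 flattened configuration (vector) or matrix of rows
#' @return integer index vector
#' @export
nearest_center <- function(clusters, d16) {
  if (!is.matrix(d16)) d16 <- matrix(d16, 1L)
  C <- clusters$centers
  G <- d16 %*% t(C)
  d2 <- outer(rowSums(d16^2), rowSums(C^2), "+") - 2 * G
  max.col(-d2, ties.method = "first")
}

MOVE_SET_TOP <- 60L
MOVE_SET_SUB <- 60L

#' Build the move set of an edge type
#'
#' Two-level clustering of the edge type's observed relative
#' placements: 60 representative configurations, each split into 60
#' sub-representatives, giving exactly 3600 leaf transforms.  Corpora
#' smaller than the move-set size are handled by sampling with
#' replacement when `relax = TRUE` (the default, intended for
#' desk-scale fixture corpora).
#'
#' @param library a `pair_library` (orientations must retain their
#'   as-observed direction, which the collectors preserve)
#' @param edge_type one of "loop-nb-53", "loop-nb-35", "wc-nb-53",
#'   "wc-nb-35", "nwc-nb", "wc-pair", "nwc-pair"
#' @param types optional base-type filter, e.g. c("G", "C")
#' @param seed RNG seed
#' @param relax allow sampling with replacement for small corpora
#' @return a `move_set`: list of 3600 `rigid_transform`s plus the
#'   hierarchy index
#' @export
build_move_set <- function(library, edge_type, types = NULL, seed = 1L,
                           relax = TRUE) {
  if (edge_type == "jump") stop("jump edges have no move set")
  sel <- filter_edge_observations(library, edge_type, types)
  n_need <- MOVE_SET_TOP * MOVE_SET_SUB
  if (length(sel) == 0L) stop("no observations for edge type ", edge_type)
  if (length(sel) < n_need && !relax) {
    stop("only ", length(sel), " observations for edge type ", edge_type,
         " (need ", n_need, "); pass relax = TRUE to sample with",
         " replacement")
  }
  M <- do.call(rbind, lapply(sel, function(o) o$d16_fwd))
  set.seed(as.integer(seed))
  k1 <- min(MOVE_SET_TOP, nrow(M))
  km1 <- kmedoids_ddm(M, k1, seed)
  top_of_leaf <- integer(0L)
  leaf_orients <- list()
  for (c in seq_len(MOVE_SET_TOP)) {
    cc <- if (c <= k1) c else ((c - 1L) %% k1) + 1L
    members <- which(km1$assign == cc)
    if (!length(members)) members <- km1$medoid_idx[cc]
    sub <- M[members, , drop = FALSE]
    k2 <- min(MOVE_SET_SUB, nrow(sub))
    km2 <- kmedoids_ddm(sub, k2, seed + c)
    idx <- km2$medoid_idx
    if (k2 < MOVE_SET_SUB) {
      idx <- c(idx, sample(idx, MOVE_SET_SUB - k2, replace = TRUE))
    }
    for (m in idx) {
      leaf_orients[[length(leaf_orients) + 1L]] <-
        sel[[members[m]]]$orient_fwd
      top_of_leaf <- c(top_of_leaf, c)
    }
  }
  transforms <- lapply(leaf_orients, orientation_to_rt)
  structure(list(edge_type = edge_type, transforms = transforms,
                 top_of_leaf = top_of_leaf,
                 top_centers = km1$centers, n_obs = length(sel)),
            class = "move_set")
}

#' Relative orientation -> edge transform (child frame in parent-local
#' coordinates)
#' @keywords internal
orientation_to_rt <- function(orient) {
  fj <- frame_from_orientation(base_frame(c(0, 0, 0), diag(3L)), orient)
  rigid_transform(fj$axes, fj$origin)
}

#' Select library observations matching an edge type
#'
#' Neighbour edges use sequence-adjacent observations in the stated
#' direction; pair edges use non-local observations, split into
#' canonical-like and the rest by DDM against the idealized canonical
#' pair configuration.
#' @keywords internal
filter_edge_observations <- function(library, edge_type, types = NULL) {
  obs <- library$obs
  if (!is.null(types)) {
    key <- canonical_pair(types[1L], types[2L])
    obs <- obs[vapply(obs, function(o) {
      paste0(o$types, collapse = "") == key
    }, logical(1L))]
  }
  rel <- vapply(obs, function(o) o$rel %||% NA_integer_, integer(1L))
  wc_like <- function(o) {
    key <- paste0(sort(o$types), collapse = "")
    if (!key %in% c("CG", "AU", "GU")) return(FALSE)
    ref <- ideal_pair_d16(o$types[1L], o$types[2L])
    ddm_vec(o$d16, ref) < 1.2
  }
  keep <- switch(edge_type,
    "loop-nb-53" = , "wc-nb-53" = rel == 1L,
    "loop-nb-35" = , "wc-nb-35" = rel == -1L,
    "nwc-nb" = abs(rel) == 1L,
    "wc-pair" = vapply(obs, wc_like, logical(1L)) & abs(rel) != 1L,
    "nwc-pair" = !vapply(obs, wc_like, logical(1L)) & abs(rel) != 1L &
      vapply(obs, function(o) o$orient$r < 12, logical(1L)),
    stop("unknown edge type ", edge_type))
  keep[is.na(keep)] <- FALSE
  if (edge_type %in% c("wc-nb-53", "wc-nb-35")) {
    # helix-context neighbours: close to the ideal helical step
    ref_fwd <- helix_step_d16()
    keep <- keep & vapply(obs, function(o) {
      ddm_vec(o$d16_fwd, ref_fwd) < 1.5
    }, logical(1L))
  }
  obs[keep]
}

#' Idealized canonical pair configuration (flattened, canonical order)
#' @keywords internal
ideal_pair_d16 <- function(t1, t2) {
  key <- paste0("ideal_d16_", canonical_pair(t1, t2))
  cached <- geometry_cache[[key]]
  if (!is.null(cached)) return(cached)
  ord <- sort(c(t1, t2))
  fr <- wc_pair_frames(ord[1L], ord[2L])
  out <- pair_configuration(fr[[1L]], fr[[2L]], ord)$d16
  geometry_cache[[key]] <- out
  out
}

#' Idealized helical-step configuration (5'->3', strand 1)
#' @keywords internal
helix_step_d16 <- function() {
  cached <- geometry_cache[["helix_step_d16"]]
  if (!is.null(cached)) return(cached)
  f0 <- helix_slot_frame(0L, "G", "C", 1L)
  f1 <- helix_slot_frame(1L, "G", "C", 1L)
  out <- pair_configuration(f0, f1, c("G", "C"))$d16
  geometry_cache[["helix_step_d16"]] <- out
  out
}
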