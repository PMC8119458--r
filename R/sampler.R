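#' Monte Carlo moves and simulated annealing on the fold tree
#'
#' The sampler keeps per-term energy caches (pair interaction matrix,
#' clash matrix, rotamer and internal vectors) so the energy change of
#' a move only recomputes terms with a changed participant; the
#' incremental delta equals the full-recompute difference to numerical
#' precision, which the test-suite checks explicitly.
#'
#' @name sampler
NULL

NODE_MOVE_MAX_T <- 0.2  # Angstrom
NODE_MOVE_MAX_R <- 2    # degrees

#' Annealing schedule
#'
#' @param t0 initial temperature (2.5 for prediction-style runs, 0.5
#'   for refinement)
#' @param cooling multiplicative cooling factor per round
#' @param t_min final temperature
#' @param step_scale multiplier on the per-round step count (1 = the
#'   full protocol; desk-scale runs use less)
#' @param w0 initial weight on the clash and internal terms
#' @param ramp_end fraction of the rounds over which the weight ramps
#'   from w0 to 1 (0.6 for exploratory prediction runs; refinement of
#'   near-native models hardens the sterics much earlier, 0.2, so the
#'   trajectory cannot drift through collapsed states it could never
#'   anneal out of at low temperature)
#' @export
anneal_schedule <- function(t0 = 0.5, cooling = 0.9, t_min = 0.01,
                            step_scale = 1, w0 = 0.05,
                            ramp_end = 0.6) {
  stopifnot(cooling > 0, cooling < 1, t0 > t_min, step_scale > 0,
            ramp_end > 0, ramp_end <= 1)
  list(t0 = t0, cooling = cooling, t_min = t_min,
       step_scale = step_scale, w0 = w0, ramp_end = ramp_end,
       global_frac = 0.5)
}

#' Temperatures of a schedule
#' @keywords internal
schedule_temps <- function(schedule) {
  temps <- c()
  t <- schedule$t0
  while (t >= schedule$t_min) {
    temps <- c(temps, t)
    t <- t * schedule$cooling
  }
  temps
}

#' Clash/internal weight ramp
#'
#' Log-linear in temperature from w0 at T0 to 1 at the temperature
#' reached after 60% of the rounds, 1 afterwards.
#' @keywords internal
ramp_weight <- function(schedule, round, n_rounds) {
  frac <- schedule$ramp_end
  if (is.null(frac)) frac <- 0.6
  end <- max(2L, ceiling(frac * n_rounds))
  if (round >= end) return(1)
  schedule$w0 + (1 - schedule$w0) * (round - 1L) / (end - 1L)
}

# ---- energy caches ---------------------------------------------------

#' Initialize the energy caches of a tree state
#' @keywords internal
init_energy_cache <- function(st, tables, params = clash_params()) {
  n <- st$n
  st$tables <- tables
  st$params <- params
  st$pair_stat <- matrix(0, n, n)   # bb + bo + oo, upper triangle
  st$pair_clash <- matrix(0, n, n)  # unweighted clash, upper triangle
  st$intra_clash <- numeric(n)
  st$rot <- numeric(n)
  st$internal <- numeric(n)         # junction i -> i+1 stored at i
  for (i in seq_len(n)) {
    st$res[[i]] <- residue_with_cache(st$res[[i]], st$frames[[i]])
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      pe <- residue_pair_energy(st$res[[i]], st$res[[j]],
                                st$frames[[i]], st$frames[[j]],
                                is_chain_neighbour(st$res[[i]],
                                                   st$res[[j]]),
                                tables, params)
      st$pair_stat[i, j] <- pe[["bb"]] + pe[["bo"]] + pe[["oo"]]
      st$pair_clash[i, j] <- pe[["clash"]]
    }
    st$intra_clash[i] <- clash_pair_energy(st$res[[i]], NULL,
                                           st$frames[[i]], NULL, FALSE,
                                           tables$clash, params)
    st$rot[i] <- node_rot_energy(st, i)
  }
  for (i in seq_len(n - 1L)) {
    st$internal[i] <- junction_energy_cached(st, i)
  }
  invisible(st)
}

node_rot_energy <- function(st, i) {
  if (!all(RIBOSE_ATOMS %in% rownames(st$res[[i]]$xyz))) return(0)
  erot(residue_ribose_local(st$res[[i]], st$frames[[i]]),
       st$tables$rot, st$types[i])
}

junction_energy_cached <- function(st, i) {
  if (st$chains[i] != st$chains[i + 1L]) return(0)
  v <- junction_internal_energy(st$res[[i]], st$res[[i + 1L]],
                                st$tables)
  if (is.na(v)) 0 else v
}

#' Total energy from the caches under given weights
#' @keywords internal
cached_total <- function(st, w_clash = 1, w_internal = 1) {
  sum(st$pair_stat) + w_clash * (sum(st$pair_clash) +
                                 sum(st$intra_clash)) +
    sum(st$rot) + w_internal * sum(st$internal)
}

# ---- proposals -------------------------------------------------------

#' Recompute all cached terms touched by a set of changed residues
#'
#' Returns the proposal: new residue records, frames, and the energy
#' delta under the given weights.  `changed` holds the residues whose
#' atoms moved.
#' @keywords internal
propose_delta <- function(st, new_res, new_frames, changed,
                          w_clash = 1, w_internal = 1) {
  n <- st$n
  for (i in changed) {
    new_res[[i]]$cache <- NULL
    new_res[[i]] <- residue_with_cache(new_res[[i]], new_frames[[i]])
  }
  in_changed <- logical(n); in_changed[changed] <- TRUE
  d_stat <- 0; d_clash <- 0; d_rot <- 0; d_int <- 0
  ps <- list(); pc <- list()
  for (i in changed) {
    for (j in seq_len(n)) {
      if (j == i || (in_changed[j] && j < i)) next
      a <- min(i, j); b <- max(i, j)
      pe <- residue_pair_energy(new_res[[a]], new_res[[b]],
                                new_frames[[a]], new_frames[[b]],
                                is_chain_neighbour(new_res[[a]],
                                                   new_res[[b]]),
                                st$tables, st$params)
      s <- pe[["bb"]] + pe[["bo"]] + pe[["oo"]]
      ps[[paste(a, b)]] <- s
      pc[[paste(a, b)]] <- pe[["clash"]]
      d_stat <- d_stat + s - st$pair_stat[a, b]
      d_clash <- d_clash + pe[["clash"]] - st$pair_clash[a, b]
    }
  }
  ic <- numeric(0L); rt_ <- numeric(0L)
  for (i in changed) {
    v <- clash_pair_energy(new_res[[i]], NULL, new_frames[[i]], NULL,
                           FALSE, st$tables$clash, st$params)
    ic[as.character(i)] <- v
    d_clash <- d_clash + v - st$intra_clash[i]
    w <- node_rot_energy_new(st, new_res[[i]], new_frames[[i]], i)
    rt_[as.character(i)] <- w
    d_rot <- d_rot + w - st$rot[i]
  }
  jn <- numeric(0L)
  juncs <- unique(c(changed - 1L, changed))
  juncs <- juncs[juncs >= 1L & juncs <= n - 1L]
  for (i in juncs) {
    v <- junction_energy_new(st, new_res, i)
    jn[as.character(i)] <- v
    d_int <- d_int + v - st$internal[i]
  }
  list(new_res = new_res, new_frames = new_frames, changed = changed,
       ps = ps, pc = pc, ic = ic, rot = rt_, jn = jn,
       dE = d_stat + w_clash * d_clash + w_internal * d_int + d_rot)
}

node_rot_energy_new <- function(st, res, frame, i) {
  if (!all(RIBOSE_ATOMS %in% rownames(res$xyz))) return(0)
  erot(residue_ribose_local(res, frame), st$tables$rot, st$types[i])
}

junction_energy_new <- function(st, new_res, i) {
  if (st$chains[i] != st$chains[i + 1L]) return(0)
  v <- junction_internal_energy(new_res[[i]], new_res[[i + 1L]],
                                st$tables)
  if (is.na(v)) 0 else v
}

#' Commit an accepted proposal into the caches
#' @keywords internal
commit_proposal <- function(st, prop) {
  for (i in prop$changed) {
    st$res[[i]] <- prop$new_res[[i]]
    st$frames[[i]] <- prop$new_frames[[i]]
  }
  for (k in names(prop$ps)) {
    ij <- as.integer(strsplit(k, " ")[[1L]])
    st$pair_stat[ij[1L], ij[2L]] <- prop$ps[[k]]
    st$pair_clash[ij[1L], ij[2L]] <- prop$pc[[k]]
  }
  for (k in names(prop$ic)) st$intra_clash[as.integer(k)] <- prop$ic[[k]]
  for (k in names(prop$rot)) st$rot[as.integer(k)] <- prop$rot[[k]]
  for (k in names(prop$jn)) st$internal[as.integer(k)] <- prop$jn[[k]]
  invisible(st)
}

#' Rebuild the phosphate of junction i -> i+1 inside a residue list
#' @keywords internal
rebuild_junction <- function(st, res, i) {
  if (i < 1L || i >= st$n) return(res)
  if (st$chains[i] != st$chains[i + 1L]) return(res)
  keep <- setdiff(rownames(res[[i + 1L]]$xyz), PHOSPHATE_ATOMS)
  base <- res[[i + 1L]]$xyz[keep, , drop = FALSE]
  ph <- rebuild_phosphate(res[[i]]$xyz, base, st$tables$torsion)
  res[[i + 1L]]$xyz <- rbind(base, ph$xyz)
  res[[i + 1L]]$cache <- NULL
  res
}

#' Apply a node move (rotamer swap or small rigid adjustment)
#'
#' Only the node's own base and ribose atoms change (plus the two
#' flanking phosphates, which are rebuilt); every other node is
#' untouched.
#'
#' @param st a `nutree` with initialized caches
#' @param i node index
#' @param kind "rotamer" or "local"
#' @param move for "rotamer" an index into the rotamer library; for
#'   "local" a list with `axis`, `angle` (degrees, |angle| < 2) and
#'   `shift` (3-vector, |shift| < 0.2)
#' @param w_clash,w_internal current term weights
#' @return a proposal (see [delta_energy()]); apply with the internal
#'   commit
#' @export
apply_node_move <- function(st, i, kind, move, w_clash = 1,
                            w_internal = 1) {
  new_res <- st$res
  new_frames <- st$frames
  if (kind == "rotamer") {
    grp <- st$tables$rot$types[[st$types[i]]]
    ribose <- grp$conformers[[move]]$local
    xyz <- assemble_residue_xyz(st$frames[[i]], st$types[i], ribose)
    old_ph <- intersect(PHOSPHATE_ATOMS, rownames(st$res[[i]]$xyz))
    xyz <- rbind(xyz, st$res[[i]]$xyz[old_ph, , drop = FALSE])
    new_res[[i]] <- base_residue(st$res[[i]]$chain, st$res[[i]]$resno,
                                 st$types[i], xyz)
  } else if (kind == "local") {
    if (vnorm(move$shift) > NODE_MOVE_MAX_T ||
        abs(move$angle) > NODE_MOVE_MAX_R) {
      stop("node move outside bounds (<0.2 A, <2 deg)")
    }
    fr <- st$frames[[i]]
    rot <- rot_axis(move$axis, deg2rad(move$angle))
    rt <- rigid_transform(rot, as.numeric(fr$origin - rot %*% fr$origin +
                                            move$shift))
    keep <- setdiff(rownames(st$res[[i]]$xyz), PHOSPHATE_ATOMS)
    xyz <- st$res[[i]]$xyz
    xyz[keep, ] <- rt_apply(rt, xyz[keep, , drop = FALSE])
    new_res[[i]] <- base_residue(st$res[[i]]$chain, st$res[[i]]$resno,
                                 st$types[i], xyz)
    new_frames[[i]] <- frame_transform(fr, rt)
  } else stop("unknown node move kind ", kind)
  new_res <- rebuild_junction(st, new_res, i - 1L)
  new_res <- rebuild_junction(st, new_res, i)
  changed <- i
  if (i < st$n && st$chains[i] == st$chains[i + 1L]) {
    changed <- c(changed, i + 1L)
  }
  propose_delta(st, new_res, new_frames, changed, w_clash, w_internal)
}

#' Apply an edge move (local wiggle or a move-set transform)
#'
#' The subtree below the edge moves rigidly: all relative placements
#' inside it are preserved exactly; phosphates bridging the boundary
#' are rebuilt.
#'
#' @param st a `nutree` with initialized caches
#' @param child child node of the edge (the edge is parent(child) ->
#'   child)
#' @param move a `rigid_transform` (new edge transform, for global
#'   moves drawn from the edge's move set) or a list with `axis`,
#'   `angle`, `shift` for a local wiggle of the current transform
#' @param w_clash,w_internal current term weights
#' @return a proposal
#' @export
apply_edge_move <- function(st, child, move, w_clash = 1,
                            w_internal = 1) {
  p <- st$parent[child]
  if (is.na(p)) stop("node ", child, " has no parent edge")
  if (st$edge_type[child] == "jump" &&
      inherits(move, "rigid_transform")) {
    stop("jump edges admit no global move set")
  }
  old_rt <- st$edge_rt[[child]]
  new_rt <- if (inherits(move, "rigid_transform")) {
    move
  } else {
    if (vnorm(move$shift) > NODE_MOVE_MAX_T ||
        abs(move$angle) > NODE_MOVE_MAX_R) {
      stop("edge move outside local bounds")
    }
    rt_compose(old_rt,
               rigid_transform(rot_axis(move$axis,
                                        deg2rad(move$angle)),
                               move$shift))
  }
  # delta transform in global coordinates
  f_child_old <- st$frames[[child]]
  f_child_new <- frame_from_relative_rt(st$frames[[p]], new_rt)
  Told <- rigid_transform(f_child_old$axes, f_child_old$origin)
  Tnew <- rigid_transform(f_child_new$axes, f_child_new$origin)
  delta <- rt_compose(Tnew, rt_invert(Told))
  sub <- subtree_nodes(st, child)
  new_res <- st$res
  new_frames <- st$frames
  for (v in sub) {
    xyz <- rt_apply(delta, st$res[[v]]$xyz)
    rownames(xyz) <- rownames(st$res[[v]]$xyz)
    colnames(xyz) <- c("x", "y", "z")
    new_res[[v]] <- base_residue(st$res[[v]]$chain, st$res[[v]]$resno,
                                 st$types[v], xyz)
    new_frames[[v]] <- frame_transform(st$frames[[v]], delta)
  }
  changed <- sub
  # rebuild phosphates crossing the boundary
  in_sub <- logical(st$n); in_sub[sub] <- TRUE
  for (i in seq_len(st$n - 1L)) {
    if (st$chains[i] != st$chains[i + 1L]) next
    if (in_sub[i] != in_sub[i + 1L]) {
      new_res <- rebuild_junction(st, new_res, i)
      changed <- unique(c(changed, i + 1L))
    }
  }
  prop <- propose_delta(st, new_res, new_frames, sort(changed),
                        w_clash, w_internal)
  prop$new_edge_rt <- new_rt
  prop$edge_child <- child
  prop
}

#' Energy change of a proposed move
#'
#' Incremental evaluation: only terms with at least one changed
#' participant are recomputed; the result equals the full-recompute
#' difference (tested to 1e-6).
#'
#' @param st a `nutree` with caches
#' @param prop a proposal from [apply_node_move()] or
#'   [apply_edge_move()]
#' @return numeric delta energy
#' @export
delta_energy <- function(st, prop) prop$dE

#' Monte Carlo simulated annealing
#'
#' Metropolis sampling over node and edge moves with geometric
#' cooling; the clash and internal terms are ramped from a low weight
#' to full strength as the temperature drops, letting large
#' rearrangements escape steric lock-in early.  Returns the
#' lowest-energy conformation visited (under full weights).
#'
#' @param st a `nutree`
#' @param tables a `refine_tables`
#' @param schedule an [anneal_schedule()]
#' @param seed RNG seed (trajectories are deterministic given the
#'   seed)
#' @param move_sets optional named list of `move_set` objects per edge
#'   type (built from the table bundle's library if absent)
#' @param verbose log per-round temperature, acceptance and best
#'   energy
#' @return list with `best` (an `rna_structure`), `best_energy`,
#'   `trace` (per-round data frame) and `final_energy`
#' @export
anneal <- function(st, tables, schedule = anneal_schedule(), seed = 1L,
                   move_sets = NULL, verbose = FALSE) {
  set.seed(as.integer(seed))
  init_energy_cache(st, tables)
  temps <- schedule_temps(schedule)
  n_rounds <- length(temps)
  if (is.null(move_sets)) move_sets <- default_move_sets(st, tables)
  n_step <- max(10L, ceiling(nutree_n_step(st) * schedule$step_scale))
  movable <- which(!is.na(st$parent))
  best_energy <- cached_total(st, 1, 1)
  best_res <- st$res
  trace <- NULL
  n_rot <- vapply(st$tables$rot$types, function(g) {
    if (is.null(g)) 0L else length(g$conformers)
  }, integer(1L))
  for (round in seq_len(n_rounds)) {
    temp <- temps[round]
    w <- ramp_weight(schedule, round, n_rounds)
    e_cur <- cached_total(st, w, w)
    acc <- 0L
    for (step in seq_len(n_step)) {
      is_node <- stats::runif(1L) < st$n / (st$n + length(movable))
      prop <- if (is_node) {
        i <- sample.int(st$n, 1L)
        if (stats::runif(1L) < 0.5 && n_rot[st$types[i]] > 1L) {
          apply_node_move(st, i, "rotamer",
                          sample.int(n_rot[st$types[i]], 1L), w, w)
        } else {
          apply_node_move(st, i, "local",
                          list(axis = unit(stats::rnorm(3L)),
                               angle = stats::runif(1L, -2, 2) * 0.95,
                               shift = stats::runif(3L, -1, 1) * 0.11),
                          w, w)
        }
      } else {
        child <- movable[sample.int(length(movable), 1L)]
        ms <- move_sets[[st$edge_type[child]]]
        gf <- schedule$global_frac
        if (is.null(gf)) gf <- 0.5
        if (!is.null(ms) && stats::runif(1L) < gf) {
          apply_edge_move(st, child,
                          ms$transforms[[sample.int(
                            length(ms$transforms), 1L)]], w, w)
        } else {
          apply_edge_move(st, child,
                          list(axis = unit(stats::rnorm(3L)),
                               angle = stats::runif(1L, -2, 2) * 0.95,
                               shift = stats::runif(3L, -1, 1) * 0.11),
                          w, w)
        }
      }
      if (metropolis_accept(prop$dE, temp)) {
        commit_proposal(st, prop)
        refresh_edge_rt(st, prop$changed)
        e_cur <- e_cur + prop$dE
        acc <- acc + 1L
        e_full <- cached_total(st, 1, 1)
        if (e_full < best_energy) {
          best_energy <- e_full
          best_res <- st$res
        }
      }
    }
    trace <- rbind(trace, data.frame(round = round, temp = temp,
                                     weight = w, accepted = acc,
                                     steps = n_step,
                                     energy = cached_total(st, 1, 1),
                                     best = best_energy))
    if (verbose) {
      message(sprintf("round %2d T=%.4f w=%.2f acc=%d/%d E=%.2f best=%.2f",
                      round, temp, w, acc, n_step,
                      cached_total(st, 1, 1), best_energy))
    }
  }
  list(best = rna_structure(best_res, id = "refined"),
       best_energy = best_energy,
       final_energy = cached_total(st, 1, 1), trace = trace)
}

#' Metropolis acceptance rule
#'
#' Accept when the energy does not increase, otherwise with
#' probability exp(-dE/T); at T -> 0 only non-increasing moves pass.
#'
#' @param dE proposed energy change
#' @param temp temperature
#' @return logical
#' @export
metropolis_accept <- function(dE, temp) {
  dE <= 0 || (temp > 0 && stats::runif(1L) < exp(-dE / temp))
}

#' Re-derive edge transforms touching moved nodes from their frames
#' @keywords internal
refresh_edge_rt <- function(st, changed) {
  affected <- unique(c(changed, unlist(st$children[changed])))
  for (v in affected) {
    if (!is.na(st$parent[v])) {
      st$edge_rt[[v]] <- frame_relative_rt(st$frames[[st$parent[v]]],
                                           st$frames[[v]])
    }
  }
  invisible(st)
}

#' Build the default move sets for a tree from the table bundle
#' @keywords internal
default_move_sets <- function(st, tables) {
  out <- list()
  for (ty in unique(st$edge_type[!is.na(st$edge_type)])) {
    if (ty == "jump") next
    out[[ty]] <- tryCatch(
      build_move_set(tables$library, ty, seed = 1L),
      error = function(e) NULL)
  }
  out
}

#' Refine a structure by simulated annealing
#'
#' High-level wrapper: builds the fold tree from the pairing
#' annotation, runs one annealing trajectory per seed and returns the
#' refined models sorted by energy.
#'
#' @param structure an `rna_structure` (near-native model to refine)
#' @param pairing a `pairing_annotation`
#' @param tables a `refine_tables`
#' @param n_models number of trajectories (seeds `seed`, `seed+1`, ...)
#' @param seed base RNG seed
#' @param mode "refine" (T0 = 0.5, cooling 0.9) or "predict"
#'   (T0 = 2.5, cooling 0.95)
#' @param step_scale step-count multiplier (1 = full protocol)
#' @param verbose log rounds
#' @return list with `models` (list of `rna_structure`), `energies`,
#'   and `traces`
#' @export
refine <- function(structure, pairing, tables, n_models = 1L,
                   seed = 1L, mode = c("refine", "predict"),
                   step_scale = 1, verbose = FALSE) {
  mode <- match.arg(mode)
  schedule <- if (mode == "refine") {
    sc <- anneal_schedule(t0 = 0.5, cooling = 0.9,
                          step_scale = step_scale, ramp_end = 0.2)
    # near-native refinement rarely benefits from library catapults;
    # keep most edge sampling local
    sc$global_frac <- 0.1
    sc
  } else {
    anneal_schedule(t0 = 2.5, cooling = 0.95, step_scale = step_scale)
  }
  models <- list(); energies <- numeric(0L); traces <- list()
  for (m in seq_len(n_models)) {
    st <- build_nutree(structure, pairing)
    out <- anneal(st, tables, schedule, seed = seed + m - 1L,
                  verbose = verbose)
    models[[m]] <- out$best
    energies[m] <- out$best_energy
    traces[[m]] <- out$trace
  }
  ord <- order(energies)
  list(models = models[ord], energies = energies[ord],
       traces = traces[ord])
}
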