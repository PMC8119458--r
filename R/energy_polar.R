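#' Base-oxygen and oxygen-oxygen hydrogen-bond energies
#'
#' Orientation-dependent polar-contact energies: a base-oxygen term
#' over the four pseudo-atom distances with a logistic distance gate
#' and a quadratic angular score, and an oxygen-oxygen term over the
#' six pairwise distances of the four defining atoms.  Unlike the
#' base-base term, the repulsive (positive log-ratio) part is retained
#' but attenuated by the distance gates.
#'
#' @name energy-polar
NULL

#' Polar energy parameters
#'
#' Kernel widths, logistic gate midpoints/rates and the reference
#' depths the table minima are scaled to.
#' @export
polar_params <- function() {
  list(bo_width = 0.16, bo_mid = 3.7, bo_rate = 0.08,
       oo_width = 0.1, oo_mid = 3.3, oo_rate = 0.07,
       bo_target = -3.0,
       oo_targets = c("O2'-O2'" = -3.0, "O2'-OP" = -2.0,
                      "OP-OP" = -1.5),
       theta_trim = 0.03,
       gated_oxygens = c("O2'", "OP"))
}

#' Quadratic angular hydrogen-bond score
#'
#' 1 at the median angle, falling quadratically to 0 at the trimmed
#' lower/upper bounds, 0 outside; continuous everywhere.
#'
#' @param theta angle(s) in degrees
#' @param range list/vector with `L`, `M`, `U` (lower bound, median,
#'   upper bound)
#' @return score(s) in [0, 1]
#' @export
angle_score_s <- function(theta, range) {
  L <- range[["L"]]; M <- range[["M"]]; U <- range[["U"]]
  s <- numeric(length(theta))
  lo <- theta > L & theta <= M
  hi <- theta > M & theta < U
  s[lo] <- 1 - ((theta[lo] - M) / (L - M))^2
  s[hi] <- 1 - ((theta[hi] - M) / (U - M))^2
  s
}

#' Logistic distance-decay gate
#'
#' `1 - 1/(1 + exp((midpoint - d)/rate))`: approximately 1 well below
#' the midpoint, 0.5 at it, approximately 0 well above; strictly
#' decreasing.
#'
#' @param d distance(s), Angstrom
#' @param midpoint gate midpoint, Angstrom
#' @param rate decay rate parameter
#' @return weight(s) in (0, 1)
#' @export
decay_weight <- function(d, midpoint, rate) {
  1 - 1 / (1 + exp((midpoint - d) / rate))
}

#' Build the polar energy tables from a contact library
#'
#' Derives the per-oxygen-class angle ranges (trimming 3% from each
#' tail), groups base-oxygen observations by (base type, oxygen type)
#' and oxygen-oxygen observations by class, and fixes each group's
#' reference density so the deepest log-ratio equals the configured
#' target.
#'
#' @param polar a `polar_library` from [collect_polar_observations()]
#' @param params see [polar_params()]
#' @return a `polar_tables` object
#' @export
build_polar_tables <- function(polar, params = polar_params()) {
  # angle ranges per gated oxygen class
  angles <- new.env(parent = emptyenv())
  for (cls in params$gated_oxygens) {
    th <- unlist(lapply(polar$bo, function(o) {
      if (o$otype == cls) o$thetas else NULL
    }))
    if (length(th) >= 10L) {
      q <- stats::quantile(th, c(params$theta_trim, 0.5,
                                 1 - params$theta_trim), names = FALSE)
      angles[[cls]] <- c(L = q[1L], M = q[2L], U = q[3L])
    }
  }
  bo <- new.env(parent = emptyenv())
  keys <- vapply(polar$bo, function(o) paste0(o$base, "|", o$otype),
                 character(1L))
  for (k in unique(keys)) {
    sel <- polar$bo[keys == k]
    M <- do.call(rbind, lapply(sel, function(o) o$d4))
    fmax <- max(kde_group_density(M, M, params$bo_width))
    bo[[k]] <- list(d4 = M, n = nrow(M),
                    f_ref = fmax * exp(params$bo_target))
  }
  oo <- new.env(parent = emptyenv())
  okeys <- vapply(polar$oo, function(o) o$class, character(1L))
  for (k in unique(okeys)) {
    sel <- polar$oo[okeys == k]
    M <- do.call(rbind, lapply(sel, function(o) o$d6))
    fmax <- max(kde_group_density(M, M, params$oo_width))
    oo[[k]] <- list(d6 = M, n = nrow(M),
                    f_ref = fmax * exp(params$oo_targets[[k]]))
  }
  structure(list(bo = bo, oo = oo, angles = angles, params = params),
            class = "polar_tables")
}

#' Gaussian KDE of query rows against library rows (RMS row distance)
#' @keywords internal
kde_group_density <- function(Q, M, width) {
  if (is.null(dim(Q))) Q <- matrix(Q, 1L)
  nc <- ncol(M)
  G <- Q %*% t(M)
  d2 <- pmax(outer(rowSums(Q^2), rowSums(M^2), "+") - 2 * G, 0) / nc
  rowSums(exp(-0.5 * d2 / width^2))
}

#' Base-oxygen interaction energy
#'
#' `E_bo = -w_bo(d_min) * s(theta) * ln f(x)/f_ref` evaluated against
#' the (base type, oxygen type) group.  When several base polar atoms
#' are in hydrogen-bond range the best angular score gates the term;
#' ungated oxygen types (O3', O4', O5') use s = 1.
#'
#' @param contact list with `base`, `otype`, `d4` (distances to the
#'   four pseudo-atoms), `dmin` (minimum distance to any base heavy
#'   atom) and `thetas` (candidate hydrogen-bond angles, degrees)
#' @param tables a `polar_tables`
#' @return energy (negative = favourable; positive values possible but
#'   gated)
#' @export
ebo <- function(contact, tables) {
  p <- tables$params
  if (!contact$otype %in% c("OP", "O2'", "O3'", "O4'", "O5'")) {
    stop("unknown oxygen type ", contact$otype)
  }
  grp <- tables$bo[[paste0(contact$base, "|", contact$otype)]]
  if (is.null(grp)) return(0)
  s <- if (contact$otype %in% p$gated_oxygens) {
    rng <- tables$angles[[contact$otype]]
    if (is.null(rng) || length(contact$thetas) == 0L) 0
    else max(angle_score_s(contact$thetas, rng))
  } else 1
  if (s == 0) return(0)
  w <- decay_weight(contact$dmin, p$bo_mid, p$bo_rate)
  f <- kde_group_density(contact$d4, grp$d4, p$bo_width)
  if (f <= 0) return(0)
  -w * s * log(f / grp$f_ref)
}

#' Oxygen-oxygen hydrogen-bond energy
#'
#' `E_oo = -w_oo(d_oo) * ln f(x)/f_ref` against the class group
#' (O2'-O2', O2'-OP or OP-OP); the angular dependence is implicit in
#' the four-atom distance representation.
#'
#' @param contact list with `class`, `d` (oxygen-oxygen distance) and
#'   `d6` (six pairwise distances of the four defining atoms)
#' @param tables a `polar_tables`
#' @return energy
#' @export
eoo <- function(contact, tables) {
  p <- tables$params
  if (!contact$class %in% names(p$oo_targets)) {
    stop("unknown oxygen-oxygen class ", contact$class)
  }
  grp <- tables$oo[[contact$class]]
  if (is.null(grp)) return(0)
  w <- decay_weight(contact$d, p$oo_mid, p$oo_rate)
  f <- kde_group_density(contact$d6, grp$d6, p$oo_width)
  if (f <= 0) return(0)
  -w * log(f / grp$f_ref)
}
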