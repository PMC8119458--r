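#' Sphere codebook: near-uniform direction quantization
#'
#' The two directional dimensions of the 6D base-base table are
#' discretized by a fixed set of near-uniformly distributed unit
#' vectors, obtained by Monte Carlo simulated annealing of points with
#' repulsive pairwise interactions proportional to the inverse squared
#' distance.  Large codebooks start from a Fibonacci lattice and are
#' polished by annealing plus a greedy descent pass; the result is
#' deterministic for a fixed seed.
#'
#' @name sphere-codebook
NULL

fibonacci_sphere <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

sphere_energy <- function(pts) {
  d2 <- as.matrix(stats::dist(pts))^2
  sum(1 / d2[upper.tri(d2)])
}

# energy contribution of point i against all others
point_energy <- function(pts, i) {
  d2 <- rowSums(sweep(pts, 2L, pts[i, ])^2)
  sum(1 / d2[-i])
}

#' Generate a sphere codebook
#'
#' @param n number of unit vectors (>= 4)
#' @param seed RNG seed; the codebook is deterministic given the seed
#' @param n_steps annealing proposals (default scales with n)
#' @return a `sphere_codebook`: matrix `vectors` (n x 3, unit rows)
#' @export
generate_sphere_codebook <- function(n, seed = 1L, n_steps = NULL) {
  if (n < 4L) stop("sphere codebook needs n >= 4 points")
  set.seed(as.integer(seed))
  pts <- if (n >= 64L) {
    fibonacci_sphere(n)
  } else {
    m <- matrix(stats::rnorm(3L * n), n, 3L)
    m / rows_norm(m)
  }
  if (is.null(n_steps)) n_steps <- if (n >= 64L) 6000L else 40000L
  # small n anneals from random placements at a temperature comparable
  # to single-point energies; large n polishes the lattice start, so the
  # schedule begins near the acceptance scale of small perturbations
  temp <- if (n >= 64L) 2 else 0.5 * n
  cool <- exp(log(1e-5 / temp) / n_steps)
  step <- if (n >= 64L) 0.35 / sqrt(n) else 1.5 / sqrt(n)
  for (it in seq_len(n_steps)) {
    i <- sample.int(n, 1L)
    e_old <- point_energy(pts, i)
    prop <- pts[i, ] + stats::rnorm(3L) * step
    prop <- prop / vnorm(prop)
    old <- pts[i, ]
    pts[i, ] <- prop
    e_new <- point_energy(pts, i)
    de <- e_new - e_old
    if (de > 0 && stats::runif(1L) > exp(-de / temp)) {
      pts[i, ] <- old
    }
    temp <- temp * cool
    if (it %% 2000L == 0L) step <- max(step * 0.7, 0.02 / sqrt(n))
  }
  # greedy polish: accept only downhill micro-moves
  for (it in seq_len(if (n >= 64L) 4000L else 20000L)) {
    i <- sample.int(n, 1L)
    e_old <- point_energy(pts, i)
    prop <- pts[i, ] + stats::rnorm(3L) * 0.02 / sqrt(n / 16)
    prop <- prop / vnorm(prop)
    old <- pts[i, ]
    pts[i, ] <- prop
    if (point_energy(pts, i) > e_old) pts[i, ] <- old
  }
  structure(list(vectors = pts, n = n, seed = seed),
            class = "sphere_codebook")
}

#' Nearest codebook index for direction vectors
#' @param codebook a `sphere_codebook`
#' @param dirs a unit 3-vector or N x 3 matrix of unit vectors
#' @return integer index (vector)
#' @export
codebook_nearest <- function(codebook, dirs) {
  if (!is.matrix(dirs)) dirs <- matrix(dirs, 1L, 3L)
  sim <- dirs %*% t(codebook$vectors)
  max.col(sim, ties.method = "first")
}

#' Minimal nearest-neighbour angle of a codebook (radians)
#' @keywords internal
codebook_min_angle <- function(codebook) {
  g <- codebook$vectors %*% t(codebook$vectors)
  diag(g) <- -1
  acos(max(-1, min(1, max(g))))
}
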