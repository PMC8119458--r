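#' Canonical base-pair geometry
#'
#' Frames for the two bases of a canonical (Watson-Crick or wobble)
#' pair, expressed in a pair-local frame: the C1'-C1' axis along x, the
#' pair plane z = 0, the pseudo-dyad along y, antiparallel base normals.
#' The free parameters (C1'-C1' distance and the two glycosidic-bond
#' angles) are solved once per pair type by least squares against
#' standard hydrogen-bond donor-acceptor distances.
#'
#' @name pair-geometry
#' @keywords internal
NULL

# donor-acceptor atom pairs and target lengths per canonical pair type
WC_TARGETS <- list(
  GC = list(atoms = list(c("N1", "N3"), c("O6", "N4"), c("N2", "O2")),
            d = c(2.92, 2.91, 2.86)),
  AU = list(atoms = list(c("N1", "N3"), c("N6", "O4")),
            d = c(2.82, 2.95)),
  GU = list(atoms = list(c("O6", "N3"), c("N1", "O2")),
            d = c(2.83, 2.79))
)

pair_frame_lr <- function(d, lam1, lam2) {
  l1 <- deg2rad(lam1); l2 <- deg2rad(lam2)
  x1 <- c(cos(l1), sin(l1), 0)
  z1 <- c(0, 0, 1)
  f1 <- base_frame(c(-d / 2, 0, 0), cbind(x1, cross3(z1, x1), z1))
  x2 <- c(-cos(l2), sin(l2), 0)
  z2 <- c(0, 0, -1)
  f2 <- base_frame(c(d / 2, 0, 0), cbind(x2, cross3(z2, x2), z2))
  list(f1, f2)
}

#' Frames of a canonical pair in the pair-local frame
#'
#' @param t1,t2 base types forming a canonical pair (GC, AU or GU in
#'   either order)
#' @return list of two `base_frame`s, in the argument order
#' @export
wc_pair_frames <- function(t1, t2) {
  key <- paste0("wc_", t1, t2)
  cached <- geometry_cache[[key]]
  if (!is.null(cached)) return(cached)
  canon <- if (paste0(t1, t2) %in% names(WC_TARGETS)) paste0(t1, t2)
           else paste0(t2, t1)
  if (!canon %in% names(WC_TARGETS)) {
    stop("not a canonical pair: ", t1, "-", t2)
  }
  tg <- WC_TARGETS[[canon]]
  ta <- substr(canon, 1L, 1L); tb <- substr(canon, 2L, 2L)
  ba <- base_template(ta); bb <- base_template(tb)
  hb_atoms <- unique(unlist(lapply(tg$atoms, identity)))
  obj <- function(p) {
    fr <- pair_frame_lr(p[1L], p[2L], p[3L])
    A <- sweep(ba %*% t(fr[[1L]]$axes), 2L, fr[[1L]]$origin, "+")
    B <- sweep(bb %*% t(fr[[2L]]$axes), 2L, fr[[2L]]$origin, "+")
    rownames(A) <- rownames(ba); rownames(B) <- rownames(bb)
    err <- vapply(seq_along(tg$d), function(i) {
      vnorm(A[tg$atoms[[i]][1L], ] - B[tg$atoms[[i]][2L], ]) - tg$d[i]
    }, numeric(1L))
    # keep non-bonding atoms apart (soft steric floor)
    D <- cross_dist(A, B)
    pen <- sum(pmax(0, 2.7 - D)^2) - sum(vapply(seq_along(tg$d),
      function(i) max(0, 2.7 - vnorm(A[tg$atoms[[i]][1L], ] -
                                       B[tg$atoms[[i]][2L], ]))^2,
      numeric(1L)))
    sum(err^2) + 2 * pen + 0.02 * (p[1L] - 10.4)^2 +
      1e-4 * (p[2L] - p[3L])^2
  }
  fit <- stats::optim(c(10.4, 55, 55), obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
  fr <- pair_frame_lr(fit$par[1L], fit$par[2L], fit$par[3L])
  out <- if (paste0(t1, t2) == canon) {
    fr
  } else {
    # flip about the pseudo-dyad (y axis) so the first-listed base is
    # always on the -x side
    dyad <- rigid_transform(rot_axis(c(0, 1, 0), pi), c(0, 0, 0))
    list(frame_transform(fr[[2L]], dyad), frame_transform(fr[[1L]], dyad))
  }
  geometry_cache[[key]] <- out
  out
}

#' Complementary base of a canonical pair
#' @keywords internal
wc_complement <- function(type) {
  c(A = "U", U = "A", G = "C", C = "G")[[type]]
}
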