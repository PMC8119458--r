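test_that("base frames follow the glycosidic construction", {
  # axis-aligned adenine: C1' at origin, N9 on x, C4 in the xy-plane
  xyz <- rbind("C1'" = c(0, 0, 0), N9 = c(1.48, 0, 0),
               C4 = c(2.2, 1.1, 0))
  res <- base_residue("A", 1L, "A", xyz)
  fr <- build_base_frame(res)
  expect_equal(fr$origin, c(0, 0, 0))
  expect_equal(fr$axes[, 1L], c(1, 0, 0))
  expect_equal(abs(fr$axes[, 3L]), c(0, 0, 1))
  expect_equal(det(fr$axes), 1, tolerance = 1e-12)
})

test_that("frame construction errors name the problem", {
  xyz <- rbind("C1'" = c(0, 0, 0), N9 = c(1.48, 0, 0))
  expect_error(build_base_frame(base_residue("A", 1L, "A", xyz)), "C4")
  collinear <- rbind("C1'" = c(0, 0, 0), N9 = c(1, 0, 0),
                     C4 = c(2, 0, 0))
  expect_error(build_base_frame(base_residue("A", 1L, "A", collinear)),
               "collinear")
  expect_error(base_residue("A", 1L, "X", rbind("C1'" = c(0, 0, 0))),
               "base type")
})

test_that("frames are equivariant under rigid motions", {
  set.seed(1)
  helix <- ideal_helix("GC")
  res <- helix$residues[[1L]]
  for (k in 1:10) {
    rt <- random_rigid()
    moved <- res
    moved$xyz <- rt_apply(rt, res$xyz)
    rownames(moved$xyz) <- rownames(res$xyz)
    f0 <- build_base_frame(res)
    f1 <- build_base_frame(moved)
    expect_equal(f1$origin, rt_apply(rt, f0$origin), tolerance = 1e-9)
    expect_equal(f1$axes, rt$R %*% f0$axes, tolerance = 1e-9)
  }
})

test_that("frame matches an independent Gram-Schmidt computation", {
  helix <- ideal_helix("GCGC")
  for (res in helix$residues[c(1L, 2L, 5L)]) {
    fr <- build_base_frame(res)
    n <- if (res$type %in% c("A", "G")) "N9" else "N1"
    cn <- if (res$type %in% c("A", "G")) "C4" else "C2"
    v1 <- res$xyz[n, ] - res$xyz["C1'", ]
    v2 <- res$xyz[cn, ] - res$xyz[n, ]
    x <- v1 / sqrt(sum(v1^2))
    zraw <- c(v1[2] * v2[3] - v1[3] * v2[2],
              v1[3] * v2[1] - v1[1] * v2[3],
              v1[1] * v2[2] - v1[2] * v2[1])
    z <- zraw / sqrt(sum(zraw^2))
    y <- c(z[2] * x[3] - z[3] * x[2],
           z[3] * x[1] - z[1] * x[3],
           z[1] * x[2] - z[2] * x[1])
    expect_equal(fr$axes, cbind(x, y, z), tolerance = 1e-10)
  }
})

test_that("relative orientation of a pure translation", {
  fi <- base_frame(c(0, 0, 0), diag(3L))
  fj <- base_frame(c(0, 0, 5), diag(3L))
  ro <- relative_orientation(fi, fj)
  expect_equal(ro$r, 5)
  expect_equal(ro$dir_ij, c(0, 0, 1))
  expect_equal(ro$dir_ji, c(0, 0, -1))
  expect_error(relative_orientation(fi, fi), "coincident")
})

test_that("exchanging the arguments swaps directions, keeps r and the twist", {
  set.seed(2)
  for (k in 1:20) {
    fi <- random_frame(); fj <- random_frame()
    a <- relative_orientation(fi, fj)
    b <- relative_orientation(fj, fi)
    expect_equal(a$r, b$r)
    expect_equal(a$dir_ij, b$dir_ji)
    expect_equal(a$dir_ji, b$dir_ij)
    # the twist about the inter-origin axis is a dihedral-like quantity
    # and is invariant under exchange
    expect_equal(a$omega, b$omega, tolerance = 1e-9)
  }
})

test_that("frame j is exactly recoverable from frame i + orientation", {
  set.seed(3)
  for (k in 1:50) {
    fi <- random_frame(); fj <- random_frame()
    ro <- relative_orientation(fi, fj)
    fj2 <- frame_from_orientation(fi, ro)
    expect_equal(fj2$origin, fj$origin, tolerance = 1e-8)
    expect_equal(fj2$axes, fj$axes, tolerance = 1e-8)
  }
})

test_that("ddm is a pseudo-metric invariant to global rigid motion", {
  set.seed(4)
  for (k in 1:20) {
    fi <- random_frame(); fj <- random_frame()
    fa <- random_frame(); fb <- random_frame()
    x <- pair_configuration(fi, fj, c("G", "C"))
    y <- pair_configuration(fa, fb, c("G", "C"))
    expect_equal(ddm(x, x), 0)
    expect_gte(ddm(x, y), 0)
    expect_equal(ddm(x, y), ddm(y, x))
    rt <- random_rigid()
    xm <- pair_configuration(frame_transform(fi, rt),
                             frame_transform(fj, rt), c("G", "C"))
    expect_equal(ddm(x, xm), 0, tolerance = 1e-9)
    expect_equal(ddm(xm, y), ddm(x, y), tolerance = 1e-9)
  }
  x <- pair_configuration(random_frame(), random_frame(), c("G", "C"))
  y <- pair_configuration(random_frame(), random_frame(), c("A", "U"))
  expect_error(ddm(x, y), "base types")
})

test_that("superposition RMSD matches a quaternion oracle", {
  # independent oracle: Horn's closed-form quaternion solution
  quaternion_rmsd <- function(A, B) {
    A <- sweep(A, 2L, colMeans(A)); B <- sweep(B, 2L, colMeans(B))
    M <- t(A) %*% B
    K <- matrix(0, 4L, 4L)
    K[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
    K[1, 2] <- K[2, 1] <- M[2, 3] - M[3, 2]
    K[1, 3] <- K[3, 1] <- M[3, 1] - M[1, 3]
    K[1, 4] <- K[4, 1] <- M[1, 2] - M[2, 1]
    K[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
    K[2, 3] <- K[3, 2] <- M[1, 2] + M[2, 1]
    K[2, 4] <- K[4, 2] <- M[3, 1] + M[1, 3]
    K[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
    K[3, 4] <- K[4, 3] <- M[2, 3] + M[3, 2]
    K[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
    lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
    sqrt(max(msd, 0))
  }
  set.seed(5)
  A <- matrix(rnorm(30), 10L, 3L)
  expect_equal(superpose_rmsd(A, A), 0)
  rt <- random_rigid()
  expect_equal(superpose_rmsd(A, rt_apply(rt, A)), 0, tolerance = 1e-9)
  for (k in 1:10) {
    A <- matrix(rnorm(30), 10L, 3L)
    B <- matrix(rnorm(30), 10L, 3L)
    expect_equal(superpose_rmsd(A, B), quaternion_rmsd(A, B),
                 tolerance = 1e-9)
  }
  expect_error(superpose_rmsd(A, B[1:5, ]), "differ in size")
})
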