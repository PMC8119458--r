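test_that("the clash energy follows its piecewise form", {
  r0 <- 3.0
  expect_equal(eclash(3.1, r0), 0)
  expect_equal(eclash(2.8, r0), (3 * 0.4)^4)       # plateau, k = 3
  expect_equal(eclash(2.8, r0), 2.0736)
  # linear branch continues the plateau with slope 4 (k s)^3
  expect_equal(eclash(2.5, r0),
               (1.2)^4 + 4 * (1.2)^3 * 0.1, tolerance = 1e-12)
  # continuity at r0 - shell
  eps <- 1e-9
  expect_lt(abs(eclash(2.6 - eps, r0) - eclash(2.6 + eps, r0)), 1e-5)
  # monotone non-increasing over the whole range
  d <- seq(0.5, 4, by = 0.001)
  e <- eclash(d, r0)
  expect_true(all(diff(e) <= 1e-12))
  expect_error(eclash(-1, r0), "non-positive")
  # supported stiffness range
  expect_equal(eclash(2.8, r0, clash_params(k_clash = 2)), (0.8)^4)
  expect_error(clash_params(k_clash = 7))
})

test_that("softened harmonic is quadratic inside and linear outside", {
  expect_equal(softened_harmonic(0), 0)
  expect_equal(softened_harmonic(1), 1)
  expect_equal(softened_harmonic(1.5), 2)
  expect_equal(softened_harmonic(-1.5), 2)
  # C1 continuity at |u| = 1: one-sided slopes both equal 2
  h <- 1e-7
  expect_equal((softened_harmonic(1 + h) - softened_harmonic(1)) / h, 2,
               tolerance = 1e-5)
  expect_equal((softened_harmonic(1) - softened_harmonic(1 - h)) / h, 2,
               tolerance = 1e-5)
})

test_that("rotamer energy is zero at the densest conformer", {
  tab <- shared_tables()
  for (ty in c("G", "C")) {
    grp <- tab$rot$types[[ty]]
    vals <- vapply(seq_len(nrow(grp$flat)), function(i) {
      erot(matrix(grp$flat[i, ], 8L, 3L), tab$rot, ty)
    }, numeric(1L))
    expect_true(all(vals >= -1e-12))
    expect_equal(min(vals), 0, tolerance = 1e-9)
  }
  expect_error(erot(matrix(0, 8L, 3L),
                    structure(list(types = list()),
                              class = "rotamer_library"), "G"),
               "empty rotamer library")
})

test_that("a 9:1 two-conformer library gives a ln 9 energy gap", {
  tab <- shared_tables()
  base_conf <- tab$rot$types$G$flat[1L, ]
  other <- base_conf + rep(c(1.5, -1.5, 1.5), length.out = 24L)
  lib <- structure(list(types = list(
    G = list(conformers = list(), flat = rbind(base_conf, other),
             weights = c(0.9, 0.1)))), class = "rotamer_library")
  e1 <- erot(matrix(base_conf, 8L, 3L), lib, "G")
  e2 <- erot(matrix(other, 8L, 3L), lib, "G")
  # in the narrow-kernel limit the gap is exactly ln(0.9/0.1)
  expect_equal(e2 - e1, log(9), tolerance = 1e-6)
})

test_that("uniform torsion tables give an angle-independent energy", {
  nb <- 36L
  uni <- structure(list(ez = array(1 / nb^2, c(2L, nb, nb)),
                        a = array(1 / nb, c(nb, nb, nb)),
                        bg = array(1 / nb^2, c(2L, nb, nb)),
                        n_obs = 0L), class = "torsion_tables")
  e1 <- etorsion(list(nu_i = -140, eps = 10, zeta = 20, alpha = 30,
                      beta = 40, gamma = 50, nu_j = -140), uni)
  e2 <- etorsion(list(nu_i = 100, eps = -170, zeta = 0, alpha = 99,
                      beta = -40, gamma = -50, nu_j = 100), uni)
  expect_equal(e1, e2)
})

test_that("helix dihedrals score at the torsion-table minimum", {
  tab <- shared_tables()
  helix <- ideal_helix("GCGC")
  a <- helix$residues[[1L]]; b <- helix$residues[[2L]]
  obs <- list(
    nu_i = pucker_nu(a$xyz),
    eps = rnarefine:::dihedral(a$xyz["C2'", ], a$xyz["C3'", ],
                               a$xyz["O3'", ], b$xyz["P", ]),
    zeta = rnarefine:::dihedral(a$xyz["C3'", ], a$xyz["O3'", ],
                                b$xyz["P", ], b$xyz["O5'", ]),
    alpha = rnarefine:::dihedral(a$xyz["O3'", ], b$xyz["P", ],
                                 b$xyz["O5'", ], b$xyz["C5'", ]),
    beta = rnarefine:::dihedral(b$xyz["P", ], b$xyz["O5'", ],
                                b$xyz["C5'", ], b$xyz["C4'", ]),
    gamma = rnarefine:::dihedral(b$xyz["O5'", ], b$xyz["C5'", ],
                                 b$xyz["C4'", ], b$xyz["O4'", ]),
    nu_j = pucker_nu(b$xyz))
  e_helix <- etorsion(obs, tab$torsion)
  # random angle combinations never score lower
  set.seed(30)
  for (k in 1:25) {
    rnd <- list(nu_i = obs$nu_i, eps = runif(1, -180, 180),
                zeta = runif(1, -180, 180), alpha = runif(1, -180, 180),
                beta = runif(1, -180, 180), gamma = runif(1, -180, 180),
                nu_j = obs$nu_j)
    expect_gte(etorsion(rnd, tab$torsion), e_helix - 1e-9)
  }
})

test_that("the total energy decomposition is additive and range-limited", {
  tab <- shared_tables()
  hp <- shared_hairpin()
  e <- total_energy(hp, tab)
  expect_equal(e$total, sum(e$terms), tolerance = 1e-9)
  # bookkeeping oracle: independent re-summation over residue pairs
  res <- hp$residues
  frames <- lapply(res, build_base_frame)
  for (i in seq_along(res)) {
    res[[i]] <- rnarefine:::residue_with_cache(res[[i]], frames[[i]])
  }
  acc <- c(bb = 0, bo = 0, oo = 0, clash = 0)
  for (i in 1:(length(res) - 1L)) {
    for (j in (i + 1L):length(res)) {
      acc <- acc + rnarefine:::residue_pair_energy(
        res[[i]], res[[j]], frames[[i]], frames[[j]],
        abs(i - j) == 1L, tab)
    }
  }
  expect_equal(e$terms[["E_bb"]], acc[["bb"]], tolerance = 1e-9)
  expect_equal(e$terms[["E_bo"]], acc[["bo"]], tolerance = 1e-9)
  expect_equal(e$terms[["E_oo"]], acc[["oo"]], tolerance = 1e-9)
  # a single nucleotide has no interaction or internal terms
  single <- rna_structure(hp$residues[3L], id = "single")
  es <- total_energy(single, tab)
  expect_equal(es$terms[["E_bb"]], 0)
  expect_equal(es$terms[["E_bo"]], 0)
  expect_equal(es$terms[["E_oo"]], 0)
  expect_equal(es$terms[["E_internal"]], 0)
  expect_gte(es$terms[["E_rot"]], 0)
  # two far-apart nucleotides have no pair terms at all
  far <- hp$residues[c(3L, 6L)]
  far[[2L]]$xyz <- sweep(far[[2L]]$xyz, 2L, c(50, 0, 0), "+")
  far[[2L]]$cache <- NULL
  ef <- total_energy(rna_structure(far, id = "far"), tab)
  expect_equal(ef$terms[["E_bb"]], 0)
  expect_equal(ef$terms[["E_bo"]], 0)
  expect_equal(ef$terms[["E_oo"]], 0)
})
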