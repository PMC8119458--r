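test_that("pair collection matches a brute-force double loop", {
  helix <- ideal_helix("GCGCGCGC")
  lib <- collect_pair_observations(list(helix))
  # independent enumeration of in-range ordered pairs
  frames <- lapply(helix$residues, build_base_frame)
  n_expected <- 0L
  for (i in seq_along(frames)) {
    for (j in seq_along(frames)) {
      if (i == j) next
      d <- sqrt(sum((frames[[j]]$origin - frames[[i]]$origin)^2))
      if (d <= 15) n_expected <- n_expected + 1L
    }
  }
  expect_equal(length(lib$obs), n_expected)
  # stacked neighbours and cross-strand partners are both present
  expect_gt(pair_group(lib, c("G", "C"), "1")$n, 0L)
  expect_gt(pair_group(lib, c("G", "C"), "2+")$n, 0L)
  # every observation respects the range cut
  expect_true(all(vapply(lib$obs, function(o) o$orient$r, numeric(1L))
                  <= 15))
})

test_that("degenerate corpora give empty or absent groups", {
  expect_error(collect_pair_observations(list()), "empty corpus")
  helix <- ideal_helix("GC")
  single <- rna_structure(helix$residues[1L], id = "single")
  lib <- collect_pair_observations(list(single))
  expect_equal(length(lib$obs), 0L)
  # two residues far beyond the 15 A window
  far <- helix$residues[1:2]
  far[[2L]]$xyz <- sweep(far[[2L]]$xyz, 2L, c(40, 0, 0), "+")
  lib2 <- collect_pair_observations(list(rna_structure(far, id = "far")))
  expect_equal(length(lib2$obs), 0L)
})

test_that("a single oxygen above a base gives one contact with the expected distances", {
  tmpl <- base_template("G")
  res_g <- base_residue("A", 1L, "G", tmpl)
  fr <- build_base_frame(res_g)
  o_local <- c(2.5, 1.0, 3.0)   # 3 A above the base plane
  o_global <- as.numeric(fr$axes %*% o_local) + fr$origin
  # carry the oxygen on a second residue whose own base sits far
  # enough away to make no contact of its own
  xyz_o <- rbind(sweep(base_template("C"), 2L, o_global + c(25, 25, 25),
                       "+"),
                 "C2'" = o_global + c(0, 0, 1.4),
                 "O2'" = o_global)
  res_o <- base_residue("A", 5L, "C", xyz_o)
  polar <- collect_polar_observations(
    list(rna_structure(list(res_g, res_o), id = "probe")))
  o2_obs <- Filter(function(o) o$otype == "O2'", polar$bo)
  expect_equal(length(o2_obs), 1L)
  expected_d4 <- sqrt(rowSums(sweep(pseudo_atom_template(), 2L,
                                    o_local)^2))
  expect_equal(o2_obs[[1L]]$d4, as.numeric(expected_d4),
               tolerance = 1e-9)
})

test_that("hydroxyl-phosphate contacts in a helix match direct computation", {
  helix <- ideal_helix("GCGC")
  polar <- collect_polar_observations(list(helix))
  o2op <- Filter(function(o) o$class == "O2'-OP", polar$oo)
  expect_gt(length(o2op), 0L)
  # re-derive one observation's six distances from the raw coordinates
  obs <- o2op[[1L]]
  expect_equal(length(obs$d6), 6L)
  expect_true(all(obs$d6 > 0))
  # no oxygens in range -> empty
  res <- helix$residues[c(1L, 8L)]
  res[[2L]]$xyz <- sweep(res[[2L]]$xyz, 2L, c(60, 0, 0), "+")
  far <- rna_structure(res, id = "far")
  expect_equal(length(collect_polar_observations(list(far))$oo), 0L)
})

test_that("rotamer collection expresses riboses in the base frame", {
  helix <- ideal_helix("GCGC")
  single <- rna_structure(helix$residues[1L], id = "single")
  lib1 <- collect_rotamers(list(single))
  expect_equal(length(lib1$types$G$conformers), 1L)
  expect_equal(lib1$types$G$weights, 1)
  # ideal helices are built C3'-endo throughout: one pucker region
  lib <- collect_rotamers(list(helix))
  nus <- unlist(lapply(lib$types, function(g) {
    if (is.null(g)) return(NULL)
    vapply(g$conformers, function(cf) cf$nu, numeric(1L))
  }))
  regions <- rnarefine:::pucker_region(nus)
  expect_equal(length(unique(regions)), 1L)
})

test_that("torsion tables are normalized conditional distributions", {
  tt <- collect_torsion_stats(list(ideal_helix("GCGCGC")))
  expect_gt(tt$n_obs, 0L)
  for (g in 1:2) {
    expect_equal(sum(tt$ez[g, , ]), 1, tolerance = 1e-9)
    expect_equal(sum(tt$bg[g, , ]), 1, tolerance = 1e-9)
  }
  sums <- apply(tt$a, c(1L, 2L), sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-9)
  # smoothing keeps every lookup finite
  e <- etorsion(list(nu_i = -140, eps = 13, zeta = 171, alpha = -60,
                     beta = 175, gamma = 55, nu_j = -140), tt)
  expect_true(is.finite(e))
})

test_that("clash radii follow the capped shortest-distance percentile", {
  corpus <- list(ideal_helix("GCGCGC"))
  tab <- estimate_r0(corpus)
  # oracle: re-collect the P|P distance sample independently
  coords <- structure_coords(corpus[[1L]], atoms = "P")
  d <- as.numeric(dist(coords))
  d <- d[d < 5]
  key <- "P|P"
  expected <- if (length(d) >= 20L) {
    min(quantile(d, 0.05, type = 1L) - 1e-6,
        rnarefine:::r0_cap("P", "P"))
  } else min(tab$fallback, rnarefine:::r0_cap("P", "P"))
  got <- tab$iso[[key]]
  if (is.null(got)) got <- min(tab$fallback, 3.5)
  expect_equal(got, as.numeric(expected), tolerance = 1e-9)
  # bonded neighbours never contribute: radii never see the P-OP1 bond
  # length (~1.5 A)
  for (k in ls(tab$iso)) expect_gt(tab$iso[[k]], 1.6)
})

test_that("orientation clustering minimizes RMS DDM and is monotone", {
  lib <- collect_pair_observations(list(ideal_helix("GCGCGCGC")))
  cl <- cluster_orientations(lib, c("G", "C"), "2+", k = 8L, seed = 1L)
  expect_equal(nrow(cl$centers), 8L)
  expect_true(all(diff(cl$trace) <= 1e-12))
  grp <- pair_group(lib, c("G", "C"), "2+")
  # objective beats a random center assignment
  set.seed(1)
  rnd_idx <- sample.int(grp$n, 8L)
  D <- rnarefine:::ddm_matrix(grp$d16)
  rnd_obj <- sqrt(mean(apply(D[, rnd_idx, drop = FALSE], 1L, min)^2))
  expect_lte(cl$objective, rnd_obj + 1e-12)
  # every observation is assigned to a center at the minimal distance
  # (helix symmetry duplicates configurations, so distinct centers can
  # tie exactly and index comparison would be order-dependent)
  for (i in seq_len(grp$n)) {
    d_all <- rnarefine:::ddm_to_all(grp$d16[i, ], cl$centers)
    expect_equal(d_all[cl$assign[i]], min(d_all), tolerance = 1e-9)
  }
  expect_error(cluster_orientations(lib, c("G", "C"), "2+", k = 5000L),
               "smaller k")
})

test_that("k distinct configurations cluster to themselves with zero objective", {
  set.seed(6)
  modes <- lapply(1:5, function(k) {
    list(frame_j = random_frame(), weight = 0.2, spread = 0)
  })
  lib <- synthetic_pair_library(modes, n = 5L, seed = 2L)
  grp <- pair_group(lib, c("G", "C"), "2+")
  # seeds may duplicate rows; deduplicate to the distinct set
  M <- unique(round(grp$d16, 9))
  km <- rnarefine:::kmedoids_ddm(M, nrow(M), seed = 1L)
  expect_equal(km$objective, 0, tolerance = 1e-9)
})

test_that("planted clusters are recovered by the medoids", {
  set.seed(7)
  m1 <- random_frame(); m2 <- random_frame()
  modes <- list(list(frame_j = m1, weight = 0.5, spread = 0.05),
                list(frame_j = m2, weight = 0.5, spread = 0.05))
  lib <- synthetic_pair_library(modes, n = 200L, seed = 3L)
  grp <- pair_group(lib, c("G", "C"), "2+")
  km <- rnarefine:::kmedoids_ddm(grp$d16, 2L, seed = 1L)
  c1 <- canonical_mode(m1, c("G", "C"))$d16
  c2 <- canonical_mode(m2, c("G", "C"))$d16
  d_centers <- sapply(list(c1, c2), function(cc) {
    min(rnarefine:::ddm_to_all(cc, km$centers))
  })
  expect_true(all(d_centers < 0.3))
})
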