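# FES projection, helix population, RMSF, contact maps.

test_that("FES of a degenerate ensemble is a single zero-F bin", {
  hel <- build_ideal_helix(aS)
  ens <- two_cluster_ensemble(hel, hel, 5, 5)
  expect_warning(f <- project_fes(ens), "single-bin")
  expect_equal(nrow(f$grid), 1)
  expect_equal(f$grid$free_energy, 0)
  expect_equal(f$basins$population, 1)
})

test_that("two-bin free-energy difference equals kT at a count ratio of e", {
  hel <- build_ideal_helix(aS)
  coil <- torsions_to_conformation(aS, rep(-140, 30), rep(140, 30))
  n1 <- 1000; n2 <- round(1000 / exp(1))
  ens <- two_cluster_ensemble(hel, coil, n1, n2)
  f <- project_fes(ens, bins = 10)
  occ <- dplyr::filter(f$grid, .data$count > 0)
  expect_equal(nrow(occ), 2)
  dF <- max(occ$free_energy) - min(occ$free_energy)
  # exact in the realised counts ...
  expect_equal(dF, f$kt * log(n1 / n2), tolerance = 1e-12)
  # ... and equal to kT = 2.3114 kJ/mol at 278 K for the e ratio
  expect_equal(dF, 2.3114, tolerance = 0.01)
  # counts reconstruct exactly from F
  expect_equal(sum(occ$count), n_frames(ens) * 1) # all frames binned
  expect_equal(occ$count / max(occ$count), exp(-occ$free_energy / f$kt),
               tolerance = 1e-12)
})

test_that("a 9:1 two-state ensemble yields two basins with the right split", {
  set.seed(40)
  hel <- build_ideal_helix(aS)
  coil <- torsions_to_conformation(aS, rep(-140, 30), rep(140, 30))
  jitter_conf <- function(base, sd = 4) {
    torsions_to_conformation(aS, base$phi + rnorm(30, 0, sd),
                             base$psi + rnorm(30, 0, sd))
  }
  n <- 500
  confs <- c(lapply(seq_len(round(0.9 * n)), function(i) jitter_conf(hel)),
             lapply(seq_len(round(0.1 * n)), function(i) jitter_conf(coil)))
  f <- project_fes(ensemble_from_conformations(confs), bins = 15)
  expect_gte(nrow(f$basins), 2)
  main <- f$basins[which.max(f$basins$population), ]
  # main basin at low RMSD with ~90 percent of the frames
  expect_lt(main$rmsd, 2)
  expect_equal(main$population, 0.9, tolerance = 3 * sqrt(0.9 * 0.1 / n) + 0.02)
})

test_that("helix population honours the window and the >= 4 run criterion", {
  hel <- build_ideal_helix(aS)
  ext <- torsions_to_conformation(aS, rep(-180, 30), rep(180, 30))
  all_h <- two_cluster_ensemble(hel, hel, 4, 4)
  expect_equal(helix_population(all_h)$helix_fraction, rep(1, 30))
  all_e <- two_cluster_ensemble(ext, ext, 4, 4)
  expect_equal(helix_population(all_e)$helix_fraction, rep(0, 30))
  half <- two_cluster_ensemble(hel, ext, 10, 10)
  expect_equal(helix_population(half)$helix_fraction, rep(0.5, 30))
  # a 3-residue helical island does not count
  phi <- rep(-180, 30); psi <- rep(180, 30)
  phi[10:12] <- -57; psi[10:12] <- -47
  island <- torsions_to_conformation(aS, phi, psi)
  ens <- two_cluster_ensemble(island, island, 2, 2)
  expect_equal(helix_population(ens)$helix_fraction, rep(0, 30))
  phi[10:13] <- -57; psi[10:13] <- -47
  island4 <- torsions_to_conformation(aS, phi, psi)
  ens4 <- two_cluster_ensemble(island4, island4, 2, 2)
  expect_equal(helix_population(ens4)$helix_fraction[10:13], rep(1, 4))
})

test_that("RMSF matches the isotropic-jitter expectation", {
  set.seed(33)
  hel <- build_ideal_helix(aS)
  n_f <- 2000; sigma <- 0.5
  rows <- memanchor:::atom_row(1:30, "CA")
  confs <- lapply(seq_len(n_f), function(f) {
    X <- hel$coords
    X[rows, ] <- X[rows, ] + rnorm(90, 0, sigma)
    new_conformation(aS, X, hel$phi, hel$psi)
  })
  ens <- ensemble_from_conformations(confs)
  r <- rmsf(ens, residues = 1:30)
  # superposition removes 6 rigid-body DOF of the 90 coordinate DOF
  shrink <- sqrt(1 - 6 / 90)
  expect_equal(mean(r$rmsf), sigma * sqrt(3) * shrink,
               tolerance = 0.05 * sigma * sqrt(3))
  # identical frames give zero everywhere; single frame errors
  flat <- two_cluster_ensemble(hel, hel, 3, 3)
  expect_equal(max(rmsf(flat, 1:30)$rmsf), 0, tolerance = 1e-9)
  expect_error(rmsf(ensemble_from_conformations(list(hel))), "2 frames")
})

test_that("hinge-like terminal motion shows larger terminal RMSF", {
  set.seed(44)
  confs <- lapply(1:200, function(f) {
    phi <- rep(-57, 30); psi <- rep(-47, 30)
    phi[1:5] <- runif(5, -180, 180); psi[1:5] <- runif(5, -180, 180)
    torsions_to_conformation(aS, phi, psi)
  })
  r <- rmsf(ensemble_from_conformations(confs), residues = 1:30)
  expect_gt(mean(r$rmsf[1:5]), 2 * mean(r$rmsf[10:25]))
})

test_that("salt-bridge occupancy recovers planted fractions exactly", {
  for (frac in c(0.30, 0.70)) {
    ens <- planted_saltbridge_ensemble(aS, frac)
    sb <- salt_bridge_occupancy(ens)
    expect_equal(sb$occupancy[sb$pair == "K6/D2"], frac, tolerance = 1e-12)
  }
  # the named candidate pairs are all present
  sb <- salt_bridge_occupancy(planted_saltbridge_ensemble(aS, 0.5))
  expect_true(all(c("K6/D2", "K10/E13", "K21/E28", "K23/E20") %in% sb$pair))
  # pairs always beyond the cutoff have zero occupancy
  hel <- build_ideal_helix(aS)
  far <- two_cluster_ensemble(hel, hel, 2, 2)
  sb2 <- salt_bridge_occupancy(far)
  expect_equal(sb2$occupancy[sb2$pair == "K6/E28"], 0)
  expect_true(all(sb2$occupancy >= 0 & sb2$occupancy <= 1))
})

test_that("occupancy is monotone in the cutoff radius", {
  set.seed(50)
  ens <- generate_helical_ensemble(aS, 150, 0.6, seed = 51)
  occ <- lapply(c(4.5, 5.0, 5.5), function(cut) {
    salt_bridge_occupancy(ens, cutoff = cut)$occupancy
  })
  expect_true(all(occ[[2]] >= occ[[1]]))
  expect_true(all(occ[[3]] >= occ[[2]]))
})

test_that("hydrophobic contacts reflect helical-face geometry", {
  hel <- build_ideal_helix(aS)
  ens_h <- two_cluster_ensemble(hel, hel, 2, 2)
  ext <- torsions_to_conformation(aS, rep(-180, 30), rep(180, 30))
  ens_e <- two_cluster_ensemble(ext, ext, 2, 2)
  # centroid pairs on the same helical face sit at 6.3-6.9 A, so the face
  # geometry is probed at a centroid-scale cutoff (the 5.0 A default serves
  # the group-distance analyses)
  hm_h <- hydrophobic_contact_map(ens_h, cutoff = 7)
  hm_e <- hydrophobic_contact_map(ens_e, cutoff = 7)
  expect_equal(hm_h$pair, hm_e$pair)
  i4 <- abs(hm_h$res_j - hm_h$res_i) == 4
  expect_gt(mean(hm_h$occupancy[i4]), mean(hm_e$occupancy[i4]))
  expect_true(all(hm_e$occupancy[i4] <= hm_h$occupancy[i4]))
  # one row per unordered pair, |i - j| >= 2
  expect_true(all(hm_h$res_j - hm_h$res_i >= 2))
  expect_false(any(duplicated(hm_h[, c("res_i", "res_j")])))
})

test_that("helix population and predictor basin weight agree in rank order", {
  hs <- c(0.2, 0.5, 0.8)
  stats <- vapply(seq_along(hs), function(k) {
    ens <- generate_helical_ensemble(aS, 200, hs[k], seed = 60 + k)
    c(hp = mean(helix_population(ens)$helix_fraction),
      w = mean(memanchor:::helix_basin_weight(ens$phi, ens$psi)))
  }, numeric(2))
  expect_equal(order(stats["hp", ]), order(stats["w", ]))
})
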