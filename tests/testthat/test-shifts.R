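# Shift tables, toy predictor, replica-averaged restraint energy.

test_that("toy predictor reduces to coil + helix delta at the basin centre", {
  hel <- build_ideal_helix(aS)
  pred <- predict_shifts(hel, residues = 6:25)
  coil <- random_coil_shifts()
  p <- shift_predictor()
  for (k in sample(nrow(pred), 10)) {
    expected <- coil[[pred$atom[k]]][match(aS$residues$aa[pred$residue[k]],
                                           coil$aa)] +
      p$dhelix[[pred$atom[k]]]
    expect_equal(pred$shift[k], expected, tolerance = 1e-12)
  }
  # far from the basin the shifts revert to coil
  far <- torsions_to_conformation(aS, rep(-140, 30), rep(140, 30))
  pf <- predict_shifts(far, residues = 6:25)
  coilv <- memanchor:::coil_shift_lookup(aS, pf$residue, pf$atom)
  expect_lt(max(abs(pf$shift - coilv)), 0.05)
  # basin weight one sd out in phi
  expect_equal(memanchor:::helix_basin_weight(-57 + 25, -47), exp(-0.5),
               tolerance = 1e-12)
  expect_error(predict_shifts(hel, atoms = "HB"), "Unknown atom")
})

test_that("shift table round-trips through TSV and rejects bad input", {
  ens <- generate_helical_ensemble(aS, 20, 0.7, seed = 4)
  tab <- synthesize_shifts(ens, noise_sd = 0.2, seed = 5)
  expect_equal(nrow(tab), 60) # residues 6-25 x {CA, CB, C}
  path <- withr::local_tempfile(fileext = ".tsv")
  write_shift_table(tab, path)
  back <- read_shift_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
  dup <- rbind(tab, tab[1, ])
  expect_error(write_shift_table(dup, path), "Duplicate")
  bad <- tab; bad$sigma[3] <- 0
  expect_error(write_shift_table(bad, path), "sigma")
})

test_that("restraint config round-trips through YAML", {
  r <- replica_restraint(k = 7.5, epsilon = 0.25, n_replicas = 2,
                         atoms = c("CA", "C"))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_restraint_config(r, path)
  r2 <- read_restraint_config(path)
  expect_equal(r2$k, 7.5)
  expect_equal(r2$epsilon, 0.25)
  expect_equal(r2$n_replicas, 2)
  expect_equal(r2$atoms, c("CA", "C"))
})

test_that("replica-averaged energy: exact match, single violation, cancellation", {
  hel <- build_ideal_helix(aS)
  M <- 4
  confs <- rep(list(hel), M)
  tab <- predict_shifts(hel, residues = 6:25)
  tab$sigma <- 0.3
  rst <- replica_restraint(k = 1, n_replicas = M)
  # averaged shifts equal experimental -> 0
  expect_equal(as.numeric(replica_averaged_energy(confs, tab, rst)), 0)
  # one nucleus off by eps + 1 ppm with k = 1 -> 1.0 kJ/mol
  tab2 <- tab
  tab2$shift[5] <- tab2$shift[5] + tab2$sigma[5] + 1
  expect_equal(as.numeric(replica_averaged_energy(confs, tab2, rst)), 1.0,
               tolerance = 1e-9)
  # permutation invariance with heterogeneous replicas
  set.seed(2)
  mix <- lapply(1:M, function(i) {
    torsions_to_conformation(aS, runif(30, -180, 180), runif(30, -180, 180))
  })
  e1 <- as.numeric(replica_averaged_energy(mix, tab, rst))
  e2 <- as.numeric(replica_averaged_energy(rev(mix), tab, rst))
  expect_equal(e1, e2, tolerance = 1e-9)
  # replica count mismatch and empty table error
  expect_error(replica_averaged_energy(mix[1:2], tab, rst), "replica")
  expect_error(replica_averaged_energy(confs, tab[0, ], rst), "Empty")
})

test_that("M = 2 opposite deviations cancel and M = 1 is the direct penalty", {
  # two replicas whose predicted shifts deviate +d and -d on one nucleus:
  # residue torsions chosen so the basin weights are symmetric around the
  # ideal-helix weight
  ch <- peptide_chain(strrep("A", 8))
  hel <- build_ideal_helix(ch)
  s <- shift_predictor()$s
  # weights w0 +/- dw via phi offsets
  off <- 20
  up <- torsions_to_conformation(ch, rep(-57, 8), rep(-47, 8))
  dn <- torsions_to_conformation(ch, rep(-57 + off, 8), rep(-47, 8))
  w_hi <- 1; w_lo <- exp(-off^2 / (2 * s^2))
  wbar <- (w_hi + w_lo) / 2
  tab <- predict_shifts(hel, residues = 2:7, atoms = "CA",
                        predictor = shift_predictor())
  coil <- memanchor:::coil_shift_lookup(ch, tab$residue, tab$atom)
  tab$shift <- coil + wbar * shift_predictor()$dhelix[["CA"]]
  tab$sigma <- 1e-6
  rst2 <- replica_restraint(k = 10, n_replicas = 2)
  e <- replica_averaged_energy(list(up, dn), tab, rst2)
  expect_equal(as.numeric(e), 0, tolerance = 1e-9)
  # M = 1 reduces to the direct flat-bottom formula
  rst1 <- replica_restraint(k = 3, n_replicas = 1)
  tab1 <- tab
  tab1$sigma <- 0.2
  e1 <- as.numeric(replica_averaged_energy(list(dn), tab1, rst1))
  pred <- predict_shifts(dn, residues = 2:7, atoms = "CA")
  direct <- 3 * sum(pmax(0, abs(pred$shift - tab1$shift) - 0.2)^2)
  expect_equal(e1, direct, tolerance = 1e-9)
})

test_that("energy is non-increasing as a replica moves toward the data", {
  ch <- peptide_chain(strrep("A", 8))
  hel <- build_ideal_helix(ch)
  tab <- predict_shifts(hel, residues = 2:7)
  tab$sigma <- 0.05
  rst <- replica_restraint(k = 5, n_replicas = 3)
  others <- rep(list(hel), 2) # fixed at the data
  offs <- seq(60, 0, by = -10)
  es <- vapply(offs, function(o) {
    mover <- torsions_to_conformation(ch, rep(-57 + o, 8), rep(-47, 8))
    as.numeric(replica_averaged_energy(c(others, list(mover)), tab, rst))
  }, numeric(1))
  expect_true(all(diff(es) <= 1e-9))
  expect_equal(es[length(es)], 0, tolerance = 1e-9)
})

test_that("back-calculation validation flags constructed violations", {
  ens <- generate_helical_ensemble(aS, 300, 0.7, seed = 31)
  exact <- synthesize_shifts(ens, noise_sd = 0, seed = 1)
  rep1 <- backcalc_validate(ens, exact)
  expect_true(all(rep1$pass))
  expect_equal(max(abs(rep1$mean_dev)), 0, tolerance = 1e-9)
  shifted <- exact
  shifted$shift[shifted$atom == "CA"] <-
    shifted$shift[shifted$atom == "CA"] +
    10 * seq_along(shifted$shift[shifted$atom == "CA"]) / 20
  rep2 <- backcalc_validate(ens, shifted)
  expect_false(rep2$pass[rep2$atom == "CA"])
  # noise below the predictor error estimate passes with SD near truth
  noisy <- synthesize_shifts(ens, noise_sd = 0.3, seed = 77)
  rep3 <- backcalc_validate(ens, noisy)
  expect_true(all(rep3$pass))
  expect_equal(mean(rep3$sd_dev), 0.3, tolerance = 0.1)
  expect_error(backcalc_validate(ens, dplyr::mutate(exact, residue = residue + 100)),
               "outside|overlap")
})
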