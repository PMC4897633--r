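# Annealing schedule bookkeeping and Monte Carlo sampler behaviour.

test_that("schedule accounting reproduces the protocol arithmetic", {
  full <- annealing_schedule(n_cycles = 417)
  acc <- schedule_accounting(full, n_replicas = 4)
  expect_equal(acc$cycle_ps, 600)
  expect_equal(acc$total_ns_per_replica, 250.2)
  expect_equal(acc$discarded_cycles, 84) # ceil(50 / 0.6)
  expect_equal(acc$collected_frames_total, 13320)
  one <- annealing_schedule(n_cycles = 1, discard_ns = 0)
  expect_equal(schedule_accounting(one, n_replicas = 1)$collected_frames_total,
               10)
  short <- annealing_schedule(n_cycles = 10, discard_ns = 50)
  expect_error(schedule_accounting(short), "exceeds")
})

test_that("physical energy is deterministic, repulsive on overlap, basin-shaped", {
  ch <- peptide_chain("MKVFLE")
  ext <- torsions_to_conformation(ch, rep(-140, 6), rep(140, 6))
  e1 <- physical_energy(ext)
  expect_true(is.finite(e1))
  expect_identical(as.numeric(e1), as.numeric(physical_energy(ext)))
  # forcing two centroids together raises the energy monotonically
  near <- ext$coords
  target <- ext$coords[memanchor:::atom_row(5L, "SC"), ]
  e_at <- function(d) {
    X <- near
    X[memanchor:::atom_row(1L, "SC"), ] <- target + c(d, 0, 0)
    as.numeric(physical_energy(new_conformation(ch, X, ext$phi, ext$psi)))
  }
  expect_gt(e_at(0.1), e_at(2))
  expect_gte(e_at(2), e_at(5))
  # torsion basin minimum beats a 30-degree offset, all else fixed
  hel <- build_ideal_helix(ch)
  off <- torsions_to_conformation(ch, rep(-57 + 30, 6), rep(-47, 6))
  et_h <- attr(physical_energy(hel), "components")[["torsion"]]
  et_o <- attr(physical_energy(off), "components")[["torsion"]]
  expect_lt(et_h, et_o)
})

test_that("identical seeds give identical sampling results", {
  ch <- peptide_chain("MKVFLEGA")
  ens0 <- generate_helical_ensemble(ch, 50, 0.8, seed = 2, persistence = 4)
  tab <- synthesize_shifts(ens0, noise_sd = 0.2, seed = 3, residues = 2:7)
  sch <- annealing_schedule(n_cycles = 4, discard_ns = 0.6)
  cfg <- sampler_config(seed = 17)
  r1 <- run_replica_annealing(ch, tab, cfg, sch)
  r2 <- run_replica_annealing(ch, tab, cfg, sch)
  expect_identical(r1$ensemble$phi, r2$ensemble$phi)
  expect_identical(r1$traces, r2$traces)
  # a different seed gives a different trajectory
  r3 <- run_replica_annealing(ch, tab, sampler_config(seed = 18), sch)
  expect_false(identical(r1$ensemble$phi, r3$ensemble$phi))
})

test_that("frame provenance respects the discard horizon and hold-low segment", {
  ch <- peptide_chain("MKVFLEGA")
  sch <- annealing_schedule(n_cycles = 6, discard_ns = 1.2) # 2 cycles
  cfg <- sampler_config(seed = 5, restraint = replica_restraint(k = 0))
  r <- run_replica_annealing(ch, NULL, cfg, sch)
  info <- r$ensemble$info
  expect_true(all(info$cycle > 2))
  expect_equal(n_frames(r$ensemble),
               schedule_accounting(sch)$collected_frames_total)
  expect_equal(sort(unique(info$replica)), 1:4)
  # collected at the hold-low temperature
  expect_true(all(info$temperature == 278))
})

test_that("flat-potential torsion marginals are uniform", {
  ch2 <- peptide_chain("AK")
  cfg <- sampler_config(seed = 11, n_replicas = 2, adapt = FALSE,
                        restraint = replica_restraint(k = 0),
                        energy = energy_params(ch2, w_torsion = 0,
                                               w_repulsion = 0))
  sch <- annealing_schedule(n_cycles = 30, t_low = 300, t_high = 300,
                            steps_per_ps = 10, frame_interval_ps = 5,
                            discard_ns = 0)
  r <- run_replica_annealing(ch2, NULL, cfg, sch)
  psis <- as.vector(r$ensemble$psi)
  ct <- table(cut(psis, seq(-180, 180, by = 20)))
  expect_gt(stats::chisq.test(ct)$p.value, 0.01)
})

test_that("fixed-temperature sampling reproduces the Boltzmann distribution", {
  # 2-residue toy: no nonbonded pairs, product measure over (phi, psi);
  # compare the sampled histogram with a fine-grid enumeration oracle
  ch2 <- peptide_chain("AK")
  cfg <- sampler_config(seed = 5, n_replicas = 2, adapt = FALSE,
                        restraint = replica_restraint(k = 0),
                        energy = energy_params(ch2, helix_depth = 5,
                                               ext_depth = 5, coop_j = 0,
                                               w_repulsion = 0))
  sch <- annealing_schedule(n_cycles = 150, t_low = 300, t_high = 300,
                            steps_per_ps = 10, frame_interval_ps = 1,
                            discard_ns = 0.6)
  r <- run_replica_annealing(ch2, NULL, cfg, sch)
  brk <- seq(-180, 180, by = 30)
  kt <- 0.0083144621 * 300
  grid <- expand.grid(phi = seq(-180 + 1.25, 180, by = 2.5),
                      psi = seq(-180 + 1.25, 180, by = 2.5))
  wrp <- memanchor:::wrap_angle
  etor <- function(phi, psi) {
    -(5 * exp(-((wrp(phi + 57))^2 + (wrp(psi + 47))^2) / (2 * 30^2)) +
        5 * exp(-((wrp(phi + 140))^2 + (wrp(psi - 135))^2) / (2 * 45^2)))
  }
  p <- exp(-etor(grid$phi, grid$psi) / kt)
  p <- p / sum(p)
  pb <- tapply(p, list(cut(grid$phi, brk), cut(grid$psi, brk)), sum)
  eb <- table(cut(as.vector(r$ensemble$phi), brk),
              cut(as.vector(r$ensemble$psi), brk)) /
    length(r$ensemble$phi)
  expect_lt(0.5 * sum(abs(eb - pb)), 0.05)
})

test_that("restraining to ideal-helix shifts drives the ensemble helical", {
  tab <- predict_shifts(build_ideal_helix(aS), residues = 6:25)
  tab$sigma <- 0.1
  sch <- annealing_schedule(n_cycles = 40, discard_ns = 6)
  r <- run_replica_annealing(aS, tab, sampler_config(seed = 21), sch)
  expect_gt(mean(helix_population(r$ensemble)$helix_fraction[6:25]), 0.6)
})

test_that("convergence check passes for stationary input and fails on drift", {
  hel <- build_ideal_helix(aS)
  flat <- two_cluster_ensemble(hel, hel, 20, 20)
  chk <- convergence_check(flat, n_blocks = 4)
  expect_true(all(chk$pass))
  # linearly drifting radius of gyration: interpolate helix -> extended
  ext <- torsions_to_conformation(aS, rep(-180, 30), rep(180, 30))
  drift <- ensemble_from_conformations(lapply(seq(0, 1, length.out = 40),
    function(a) {
      torsions_to_conformation(aS, (1 - a) * hel$phi + a * ext$phi,
                               (1 - a) * hel$psi + a * ext$psi)
    }))
  chk2 <- convergence_check(drift, n_blocks = 8)
  expect_false(chk2$pass[chk2$metric == "radius_of_gyration"])
})
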