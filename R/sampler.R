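# Four-replica simulated-annealing Metropolis sampler in torsion space with
# replica-averaged chemical-shift restraints, plus schedule bookkeeping and
# convergence reporting. The nominal "ps" is a bookkeeping unit mapped to MC
# sweeps (steps_per_ps); one sweep proposes one single-angle move per residue.

#' Coarse physical-energy parameters
#'
#' The stand-in potential has two torsion basins per residue (helical at
#' (-57, -47), extended at (-140, 135); Gaussian wells with documented depths
#' and widths) and a soft-sphere excluded-volume penalty between non-bonded
#' CA/sidechain centroids of residues at least two apart
#' (k_rep (r0 - r)^2 for r below r0, with r0 the sum of site radii) — finite
#' everywhere and monotonically increasing as two centroids overlap. Term
#' weights allow switching parts off (a flat potential has `w_torsion = 0`).
#'
#' A nearest-neighbour cooperativity term `-J * sum_i g_i g_(i+1)` (with g a
#' Gaussian helical-state weight) mimics the hydrogen-bond cooperativity of
#' helix formation that the per-residue basins alone cannot represent; it is
#' scaled by `w_torsion` together with the basin term.
#'
#' @param chain An [peptide_chain()].
#' @param helix_depth,ext_depth Basin depths, kJ/mol (scalar or per residue).
#' @param helix_width,ext_width Basin widths, degrees.
#' @param repulsion_k Excluded-volume force constant, kJ/mol/A^2.
#' @param ca_radius CA site radius, Angstrom.
#' @param coop_j Helix cooperativity coupling J, kJ/mol.
#' @param coop_width Width of the cooperativity state weight, degrees.
#' @param w_torsion,w_repulsion Term weights.
#' @return A parameter list consumed by [physical_energy()] and the sampler.
#' @export
energy_params <- function(chain, helix_depth = 5.5, ext_depth = 3,
                          helix_width = 30, ext_width = 45,
                          repulsion_k = 10, ca_radius = 2.0,
                          coop_j = 6, coop_width = 30,
                          w_torsion = 1, w_repulsion = 1) {
  list(n = chain$n,
       helix_depth = rep_len(helix_depth, chain$n),
       ext_depth = rep_len(ext_depth, chain$n),
       helix_width = helix_width, ext_width = ext_width,
       helix_centre = c(-57, -47), ext_centre = c(-140, 135),
       repulsion_k = repulsion_k, ca_radius = ca_radius,
       sc_radius = chain$residues$sc_radius,
       coop_j = coop_j, coop_width = coop_width,
       w_torsion = w_torsion, w_repulsion = w_repulsion)
}

#' Coarse physical energy of a conformation
#'
#' @param conf An `ma_conformation`.
#' @param params See [energy_params()]; defaults are built from the chain.
#' @return Energy in kJ/mol with attribute `components`.
#' @export
physical_energy <- function(conf, params = NULL) {
  if (is.null(params)) params <- energy_params(conf$chain)
  e <- cpp_physical_energy(conf$phi, conf$psi, conf$coords, params)
  structure(e$total, components = c(torsion = e$torsion,
                                    cooperativity = e$cooperativity,
                                    repulsion = e$repulsion))
}

#' Annealing schedule
#'
#' Each cycle is hold-low / heat / hold-high / cool with the default segment
#' durations (100, 100, 100, 300) ps between 278 and 350 K; temperature ramps
#' are linear in segment time. Frames are collected only from the hold-low
#' segment, every `frame_interval_ps`, after a discard horizon rounded up to
#' whole cycles.
#'
#' @param n_cycles Number of annealing cycles.
#' @param t_low,t_high Temperatures, K.
#' @param segment_ps Segment durations, ps.
#' @param steps_per_ps MC sweeps per nominal ps.
#' @param frame_interval_ps Collection interval within hold-low, ps.
#' @param discard_ns Initial equilibration to discard, ns (rounded up to
#'   whole cycles).
#' @return An object of class `ma_schedule`.
#' @export
annealing_schedule <- function(n_cycles, t_low = 278, t_high = 350,
                               segment_ps = c(100, 100, 100, 300),
                               steps_per_ps = 10, frame_interval_ps = 10,
                               discard_ns = 50) {
  stopifnot(n_cycles >= 1, t_low > 0, t_high > 0, length(segment_ps) == 4,
            all(segment_ps > 0), steps_per_ps >= 1, frame_interval_ps >= 1,
            discard_ns >= 0)
  structure(list(n_cycles = as.integer(n_cycles), t_low = t_low,
                 t_high = t_high, segment_ps = segment_ps,
                 steps_per_ps = as.integer(steps_per_ps),
                 frame_interval_ps = frame_interval_ps,
                 discard_ns = discard_ns),
            class = "ma_schedule")
}

#' Schedule arithmetic
#'
#' Pure bookkeeping, no sampling: cycle length, total nominal sampling per
#' replica, discarded cycles (discard horizon rounded up to whole cycles) and
#' the total number of collected conformations across replicas.
#'
#' @param schedule An [annealing_schedule()].
#' @param n_replicas Replica count M.
#' @return List with `cycle_ps`, `total_ns_per_replica`, `discarded_cycles`,
#'   `collected_frames_total`.
#' @export
schedule_accounting <- function(schedule, n_replicas = 4) {
  cycle_ps <- sum(schedule$segment_ps)
  total_ns <- schedule$n_cycles * cycle_ps / 1000
  disc <- ceiling(schedule$discard_ns * 1000 / cycle_ps)
  if (disc > schedule$n_cycles) {
    abort("Discard horizon exceeds the schedule.")
  }
  frames_per_cycle <- floor(schedule$segment_ps[1] / schedule$frame_interval_ps)
  list(cycle_ps = cycle_ps,
       total_ns_per_replica = total_ns,
       discarded_cycles = as.integer(disc),
       collected_frames_total = (schedule$n_cycles - disc) *
         frames_per_cycle * n_replicas)
}

#' Sampler configuration
#'
#' @param seed Master RNG seed (integer); per-replica streams are derived
#'   from it and are distinct.
#' @param n_replicas Replica count M.
#' @param move_width Gaussian single-angle proposal width, degrees. During
#'   the discard horizon the width is adapted per replica toward a 30-50
#'   percent acceptance rate, then frozen for collection.
#' @param adapt Adapt the move width during the discard horizon?
#' @param restraint An [replica_restraint()]; `k = 0` disables restraints.
#' @param predictor The restraining [shift_predictor()].
#' @param energy Optional [energy_params()]; built from the chain otherwise.
#' @return An object of class `ma_sampler_config`.
#' @export
sampler_config <- function(seed, n_replicas = 4, move_width = 15,
                           adapt = TRUE, restraint = replica_restraint(),
                           predictor = shift_predictor(), energy = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1, move_width > 0,
            n_replicas >= 1)
  seeds <- as.double(seed) * 1000003 + seq_len(n_replicas)
  structure(list(seed = as.integer(seed), seeds = seeds,
                 n_replicas = as.integer(n_replicas),
                 move_width = move_width, adapt = adapt,
                 restraint = restraint, predictor = predictor,
                 energy = energy),
            class = "ma_sampler_config")
}

# map a shift table to the flat nucleus arrays the C++ sampler consumes
restraint_arrays <- function(chain, table, restraint, predictor) {
  if (is.null(table) || restraint$k == 0) {
    return(list(k = 0, s = predictor$s))
  }
  table <- validate_shift_table(table, chain)
  table <- dplyr::filter(table, .data$atom %in% restraint$atoms)
  if (nrow(table) == 0) abort("Empty shift table after nucleus filtering.")
  eps <- if (is.null(restraint$epsilon)) table$sigma else
    rep_len(restraint$epsilon, nrow(table))
  list(k = restraint$k, s = predictor$s,
       res = as.integer(table$residue - 1L),
       atom = match(table$atom, SHIFT_ATOMS) - 1L,
       coil = coil_shift_lookup(chain, table$residue, table$atom) +
         unname(predictor$coil_offset[table$atom]),
       dhel = unname(predictor$dhelix[table$atom]),
       target = table$shift, eps = eps)
}

#' Run replica-averaged restrained annealing
#'
#' M replicas evolve in lockstep through the annealing cycles; each MC sweep
#' proposes one phi-or-psi Gaussian perturbation per residue, accepted by
#' Metropolis on the coarse physical energy plus the replica-averaged
#' restraint at the current segment temperature. Replicas couple only through
#' the restraint average (no replica exchange). Fully reproducible given the
#' config seed.
#'
#' @param chain An [peptide_chain()].
#' @param shift_table Experimental/synthetic shift table, or `NULL` for an
#'   unrestrained run.
#' @param config An [sampler_config()].
#' @param schedule An [annealing_schedule()].
#' @param init Optional list with `phi`, `psi` (M x n matrices, degrees) of
#'   starting torsions; random conformations (uniform torsions) otherwise.
#' @return An object of class `ma_sampling`: `ensemble`, `traces`,
#'   `frame_energies`, `accounting`, `config`, `schedule`.
#' @export
run_replica_annealing <- function(chain, shift_table = NULL, config,
                                  schedule, init = NULL) {
  acc <- schedule_accounting(schedule, config$n_replicas)
  if (acc$collected_frames_total <= 0) {
    abort("Schedule collects no frames (discard too long).")
  }
  energy <- config$energy %||% energy_params(chain)
  rst <- restraint_arrays(chain, shift_table, config$restraint,
                          config$predictor)
  seg_sweeps <- as.integer(round(schedule$segment_ps * schedule$steps_per_ps))
  seg_temp <- rbind(c(schedule$t_low, schedule$t_low),
                    c(schedule$t_low, schedule$t_high),
                    c(schedule$t_high, schedule$t_high),
                    c(schedule$t_high, schedule$t_low))
  arg <- list(n_res = chain$n, n_replicas = config$n_replicas,
              sc_dist = chain$residues$sc_dist, energy = energy,
              restraint = rst,
              schedule = list(
                n_cycles = schedule$n_cycles, seg_sweeps = seg_sweeps,
                seg_temp = seg_temp,
                discard_cycles = schedule_accounting(schedule)$discarded_cycles,
                collect_every = as.integer(schedule$frame_interval_ps *
                                             schedule$steps_per_ps)),
              move_width = config$move_width, adapt = config$adapt,
              seeds = config$seeds,
              init_phi = init$phi, init_psi = init$psi)
  res <- cpp_run_annealing(arg)
  info <- tibble::tibble(frame = seq_along(res$replica),
                         replica = res$replica, cycle = res$cycle,
                         temperature = schedule$t_low)
  ens <- new_ensemble(chain, res$phi, res$psi, info = info)
  traces <- tibble::as_tibble(res$trace)
  frame_energies <- tibble::tibble(frame = info$frame, replica = info$replica,
                                   cycle = info$cycle,
                                   e_physical = res$e_physical,
                                   e_restraint = res$e_restraint)
  structure(list(ensemble = ens, traces = traces,
                 frame_energies = frame_energies, accounting = acc,
                 config = config, schedule = schedule),
            class = "ma_sampling")
}

#' @export
print.ma_sampling <- function(x, ...) {
  cat("<ma_sampling> ", n_frames(x$ensemble), " collected frames, ",
      x$schedule$n_cycles, " cycles x ", x$config$n_replicas,
      " replicas\n", sep = "")
  invisible(x)
}

# ------------------------------------------------------------ convergence --

#' Block time series of the four convergence metrics
#'
#' The ensemble is split into `n_blocks` consecutive blocks; per block the
#' function reports (i) the Calpha RMSD between the running-mean structure up
#' to this block and up to the previous one, (ii) the circular RMSD of the
#' block-mean backbone dihedrals to the full-ensemble mean, (iii) the mean
#' radius of gyration and (iv) the mean SASA (evaluated on an even subsample
#' of at most `sasa_frames` frames per block).
#'
#' @param ens An `ma_ensemble` with at least 2 frames.
#' @param n_blocks Number of blocks.
#' @param sasa_frames SASA subsample size per block.
#' @return Tibble: `block`, `rmsd_running_mean`, `dihedral_rmsd`,
#'   `radius_of_gyration`, `sasa`.
#' @export
convergence_metrics <- function(ens, n_blocks = 10, sasa_frames = 20) {
  f <- n_frames(ens)
  if (f < 2) abort("Need at least 2 frames for block statistics.")
  n_blocks <- min(n_blocks, f)
  n <- ens$chain$n
  idx <- split(seq_len(f), cut(seq_len(f), n_blocks, labels = FALSE))
  # superpose all frames onto frame 1 (all CA) once
  ref <- ens$coords[atom_row(seq_len(n), "CA"), , 1]
  ca <- lapply(seq_len(f), function(fr) {
    P <- ens$coords[atom_row(seq_len(n), "CA"), , fr]
    apply_kabsch(P, kabsch(P, ref))
  })
  circ_mean <- function(M) { # column-wise circular mean, degrees
    atan2(colMeans(sinpi(M / 180)), colMeans(cospi(M / 180))) * 180 / pi
  }
  tor <- cbind(ens$phi[, -1, drop = FALSE], ens$psi)
  overall_tor <- circ_mean(tor)
  run_mean <- NULL
  prev_mean <- NULL
  out <- vector("list", n_blocks)
  seen <- 0
  for (b in seq_len(n_blocks)) {
    fr <- idx[[b]]
    blk_sum <- Reduce(`+`, ca[fr])
    run_mean <- if (is.null(run_mean)) blk_sum else run_mean + blk_sum
    seen <- seen + length(fr)
    cur_mean <- run_mean / seen
    rmsd_rm <- if (is.null(prev_mean)) 0 else
      sqrt(mean(rowSums((cur_mean - prev_mean)^2)))
    prev_mean <- cur_mean
    dih <- dihedral_rmsd(circ_mean(tor[fr, , drop = FALSE]), overall_tor)
    rg <- mean(vapply(fr, function(i) {
      radius_of_gyration(ens$coords[, , i])
    }, numeric(1)))
    sfr <- fr[unique(round(seq(1, length(fr),
                               length.out = min(sasa_frames, length(fr)))))]
    sa <- mean(vapply(sfr, function(i) {
      as.numeric(sasa(ensemble_conformation(ens, i)))
    }, numeric(1)))
    out[[b]] <- tibble::tibble(block = b, rmsd_running_mean = rmsd_rm,
                               dihedral_rmsd = dih, radius_of_gyration = rg,
                               sasa = sa)
  }
  dplyr::bind_rows(out)
}

#' Convergence check on the four ensemble metrics
#'
#' A metric passes when its drift — the absolute difference between the mean
#' over the last and first half of the blocks (for the running-mean-structure
#' RMSD, the maximum over the last half, which tends to zero on convergence)
#' — falls below its threshold.
#'
#' @param ens An `ma_ensemble` (or a metric tibble from
#'   [convergence_metrics()]).
#' @param thresholds Named thresholds; defaults documented in the vignette.
#' @param n_blocks Blocks to use when `ens` is an ensemble.
#' @return Tibble: `metric`, `drift`, `threshold`, `pass`.
#' @export
convergence_check <- function(ens,
                              thresholds = c(rmsd_running_mean = 0.5,
                                             dihedral_rmsd = 15,
                                             radius_of_gyration = 0.5,
                                             sasa = 60),
                              n_blocks = 10) {
  m <- if (inherits(ens, "ma_ensemble")) {
    convergence_metrics(ens, n_blocks = n_blocks)
  } else {
    ens
  }
  if (nrow(m) < 2) abort("Too few blocks for a convergence check.")
  half <- seq_len(floor(nrow(m) / 2))
  last <- seq(nrow(m) - length(half) + 1, nrow(m))
  drift <- c(
    rmsd_running_mean = max(m$rmsd_running_mean[last]),
    dihedral_rmsd = abs(mean(m$dihedral_rmsd[last]) -
                          mean(m$dihedral_rmsd[half])),
    radius_of_gyration = abs(mean(m$radius_of_gyration[last]) -
                               mean(m$radius_of_gyration[half])),
    sasa = abs(mean(m$sasa[last]) - mean(m$sasa[half]))
  )
  thr <- unname(thresholds[names(drift)])
  tibble::tibble(metric = names(drift), drift = unname(drift),
                 threshold = thr, pass = unname(drift) <= thr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
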