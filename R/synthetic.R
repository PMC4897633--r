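# Synthetic-data generators with known ground truth: helical/coil ensembles,
# placements at specified tilt/depth, noisy shift tables. All are
# bit-reproducible given their seed.

#' Generate a partially helical ensemble with known ground truth
#'
#' Per frame, residues are assigned helical/coil states by a two-state Markov
#' chain with stationary helical fraction `h` and mean helical run length
#' `persistence` (so the >= 4-run helix criterion is exercised
#' realistically). Helical residues draw torsions from
#' Normal((-57, -47), `helix_sd`); coil residues draw uniformly over the
#' torus. The realised helical-state fraction is recorded as ground truth.
#'
#' @param chain An [peptide_chain()].
#' @param n_frames Number of frames.
#' @param h Target helical fraction in \[0, 1\].
#' @param seed RNG seed (mandatory).
#' @param persistence Mean helical run length, residues.
#' @param helix_sd SD of helical torsions, degrees.
#' @return An `ma_ensemble` with attributes `helicity_truth` (realised
#'   mean helical-state fraction) and `state_truth` (frames x residues
#'   logical matrix).
#' @export
generate_helical_ensemble <- function(chain, n_frames, h, seed,
                                      persistence = 8, helix_sd = 10) {
  stopifnot(h >= 0, h <= 1, n_frames >= 1)
  with_seed(seed, {
    n <- chain$n
    if (h >= 1) {
      p_hh <- 1; p_ch <- 1
    } else if (h <= 0) {
      p_hh <- 0; p_ch <- 0
    } else {
      p_hh <- 1 - 1 / persistence
      p_ch <- (1 - p_hh) * h / (1 - h)
      if (p_ch > 1) { # persistence unattainable at this h; keep h stationary
        p_ch <- 1
        p_hh <- 1 - (1 - h) / h
      }
    }
    states <- matrix(FALSE, n_frames, n)
    for (f in seq_len(n_frames)) {
      s <- logical(n)
      s[1] <- runif(1) < h
      for (i in 2:n) {
        s[i] <- runif(1) < (if (s[i - 1]) p_hh else p_ch)
      }
      states[f, ] <- s
    }
    phi <- matrix(runif(n_frames * n, -180, 180), n_frames, n)
    psi <- matrix(runif(n_frames * n, -180, 180), n_frames, n)
    nh <- sum(states)
    phi[states] <- rnorm(nh, -57, helix_sd)
    psi[states] <- rnorm(nh, -47, helix_sd)
    ens <- new_ensemble(chain, phi, psi)
    attr(ens, "helicity_truth") <- mean(states)
    attr(ens, "state_truth") <- states
    ens
  })
}

#' Synthesise a noisy chemical-shift table from an ensemble
#'
#' Ensemble-mean predicted shifts plus i.i.d. Gaussian noise; the sigma
#' column records `noise_sd` (floored at 1e-6 so the table invariant
#' sigma > 0 holds for noise-free tables). Restricted by default to the
#' assigned region (residues 6-25) and backbone carbons CA, CB, C.
#'
#' @param ens An `ma_ensemble`.
#' @param noise_sd Noise SD, ppm.
#' @param seed RNG seed.
#' @param residues Residue selection (default 6-25).
#' @param atoms Nuclei.
#' @param predictor An [shift_predictor()].
#' @return A shift tibble (`residue`, `atom`, `shift`, `sigma`).
#' @export
synthesize_shifts <- function(ens, noise_sd = 0.3, seed = 1, residues = NULL,
                              atoms = SHIFT_ATOMS,
                              predictor = shift_predictor()) {
  if (n_frames(ens) < 1) abort("Empty ensemble.")
  with_seed(seed, {
    tab <- ensemble_mean_shifts(ens, residues = residues, atoms = atoms,
                                predictor = predictor)
    tab$shift <- tab$shift + rnorm(nrow(tab), 0, noise_sd)
    tab$sigma <- max(noise_sd, 1e-6)
    tab
  })
}

# rotation matrix taking unit vector a to unit vector b
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # opposite: rotate 180 about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a; v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
}

#' Place a peptide on a bilayer at a given tilt and anchor depth
#'
#' Rotates the conformation so its helix axis (N to C) makes the requested
#' tilt with the membrane plane, N-terminal end deeper, then translates it so
#' the anchor residue's sidechain centroid sits at `anchor_depth` above the
#' midplane, laterally at the box centre plus `lateral`. Tilt must lie in
#' \[0, 90\] degrees (hard bounds; out-of-range requests error). Errors when
#' the placement clashes with more than half the lipids.
#'
#' @param conf An `ma_conformation`.
#' @param bilayer An `ma_bilayer`.
#' @param tilt Requested tilt, degrees.
#' @param anchor_depth Depth of the anchor residue centroid above the
#'   midplane, Angstrom.
#' @param anchor_residue Residue index of the anchor.
#' @param lateral Length-2 lateral offset from the box centre, Angstrom.
#' @param axis_residues Residues defining the helix axis (default 6-25).
#' @return The positioned `ma_conformation`.
#' @export
place_peptide <- function(conf, bilayer, tilt, anchor_depth, anchor_residue,
                          lateral = c(0, 0), axis_residues = NULL) {
  if (tilt < 0 || tilt > 90) abort("`tilt` must lie in [0, 90] degrees.")
  axis_residues <- default_range(conf$chain, axis_residues)
  ax <- helix_axis(conf, axis_residues)
  target <- c(cos(tilt * pi / 180), 0, sin(tilt * pi / 180))
  R <- rotation_between(ax$axis, target)
  X <- sweep(conf$coords, 2, ax$centre) %*% t(R)
  anchor <- X[atom_row(anchor_residue, "SC"), ]
  centre <- c(bilayer$box[["x"]] / 2 + lateral[1],
              bilayer$box[["y"]] / 2 + lateral[2], anchor_depth)
  X <- sweep(X, 2, centre - anchor, "+")
  # clash check: lipids with any site within 1.5 A of a peptide site
  L <- as.matrix(bilayer$sites[, c("x", "y", "z")])
  clash_site <- rep(FALSE, nrow(L))
  for (i in seq_len(nrow(X))) {
    d2 <- (L[, 1] - X[i, 1])^2 + (L[, 2] - X[i, 2])^2 + (L[, 3] - X[i, 3])^2
    clash_site <- clash_site | d2 < 1.5^2
  }
  frac <- length(unique(bilayer$sites$lipid[clash_site])) /
    nrow(bilayer$lipids)
  if (frac > 0.5) abort("Placement clashes with more than half the lipids.")
  new_conformation(conf$chain, X, conf$phi, conf$psi)
}

#' Laterally scattered placement ensemble
#'
#' Repeats [place_peptide()] at lateral positions drawn uniformly over the
#' central region of the bilayer patch (a margin keeps the peptide away from
#' the edges), emulating fast lateral diffusion of the bound peptide over
#' the lipids. This is the ensemble on which frame-averaged depth, contact
#' and PRE analyses are meaningful.
#'
#' @inheritParams place_peptide
#' @param n_frames Number of placements.
#' @param seed RNG seed.
#' @param margin Edge margin, Angstrom.
#' @param depth_jitter SD of per-frame depth jitter, Angstrom.
#' @return An `ma_ensemble`.
#' @export
scatter_placements <- function(conf, bilayer, n_frames, tilt, anchor_depth,
                               anchor_residue, seed, margin = 25,
                               depth_jitter = 0.5, axis_residues = NULL) {
  with_seed(seed, {
    half_x <- max(bilayer$box[["x"]] / 2 - margin, 1)
    half_y <- max(bilayer$box[["y"]] / 2 - margin, 1)
    confs <- lapply(seq_len(n_frames), function(f) {
      place_peptide(conf, bilayer, tilt,
                    anchor_depth + rnorm(1, 0, depth_jitter),
                    anchor_residue,
                    lateral = c(runif(1, -half_x, half_x),
                                runif(1, -half_y, half_y)),
                    axis_residues = axis_residues)
    })
    ensemble_from_conformations(confs)
  })
}
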