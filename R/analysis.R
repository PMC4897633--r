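# Conformational analyses of refined ensembles: free-energy surface on
# (Calpha-RMSD-to-ideal-helix, dipole moment), per-residue helix population,
# RMSF, and salt-bridge / hydrophobic contact occupancies.

KB_KJ <- 0.0083144621 # kJ/mol/K

#' Per-frame projection coordinates
#'
#' Calpha RMSD to the ideal helix and dipole moment, both over the assigned
#' region (default residues 6-25; residues 1-5 and 26-30 are excluded from
#' the coordinates).
#'
#' @param ens An `ma_ensemble`.
#' @param residues Residue range for both coordinates.
#' @return Tibble: `frame`, `rmsd`, `dipole`.
#' @export
fes_coordinates <- function(ens, residues = NULL) {
  residues <- default_range(ens$chain, residues)
  ref <- build_ideal_helix(ens$chain)
  purrr::map_dfr(seq_len(n_frames(ens)), function(f) {
    cf <- ensemble_conformation(ens, f)
    tibble::tibble(frame = f, rmsd = rmsd_ca(cf, ref, residues),
                   dipole = dipole_moment(cf, residues))
  })
}

#' Free-energy surface on (RMSD to ideal helix, dipole moment)
#'
#' Two-dimensional histogram of the per-frame projection coordinates;
#' occupied bins get `F = -kT log(n / n_max)` so the most populated bin sits
#' at 0 and all free energies are >= 0 (the figure convention that colours
#' the deepest basin most negative is a sign flip of the same quantity).
#' Unoccupied bins are `NA`, not 0. Basins are local minima of F on the grid
#' (8-neighbour), with populations assigned by steepest descent; minima whose
#' catchment holds less than `min_population` of the frames are dropped as
#' histogram noise.
#'
#' @param ens An `ma_ensemble`.
#' @param residues Residue range of the projection (default 6-25).
#' @param bins Bins per axis (grid spans the observed ranges padded 5
#'   percent).
#' @param temperature Temperature in K entering kT.
#' @param min_population Minimum population share for a reported basin.
#' @return An object of class `ma_fes`: `grid` (long tibble), `basins`,
#'   `coords`, `temperature`, `kt`.
#' @export
project_fes <- function(ens, residues = NULL, bins = 40, temperature = 278,
                        min_population = 0.01) {
  if (n_frames(ens) < 1) abort("Empty ensemble.")
  xy <- fes_coordinates(ens, residues)
  kt <- KB_KJ * temperature
  degenerate <- diff(range(xy$rmsd)) < 1e-9 && diff(range(xy$dipole)) < 1e-9
  if (degenerate) {
    warn("All frames project to one point; returning a single-bin grid.")
    grid <- tibble::tibble(ix = 1L, iy = 1L, rmsd = xy$rmsd[1],
                           dipole = xy$dipole[1], count = nrow(xy),
                           free_energy = 0)
    basins <- tibble::tibble(basin = 1L, rmsd = xy$rmsd[1],
                             dipole = xy$dipole[1], free_energy = 0,
                             population = 1)
    return(structure(list(grid = grid, basins = basins, coords = xy,
                          temperature = temperature, kt = kt,
                          breaks = NULL),
                     class = "ma_fes"))
  }
  pad <- function(r) r + c(-1, 1) * 0.05 * max(diff(r), 1e-6)
  bx <- seq(pad(range(xy$rmsd))[1], pad(range(xy$rmsd))[2], length.out = bins + 1)
  by <- seq(pad(range(xy$dipole))[1], pad(range(xy$dipole))[2],
            length.out = bins + 1)
  ix <- findInterval(xy$rmsd, bx, rightmost.closed = TRUE)
  iy <- findInterval(xy$dipole, by, rightmost.closed = TRUE)
  cnt <- matrix(0L, bins, bins)
  for (k in seq_len(nrow(xy))) cnt[ix[k], iy[k]] <- cnt[ix[k], iy[k]] + 1L
  fmat <- matrix(NA_real_, bins, bins)
  occ <- cnt > 0
  fmat[occ] <- -kt * log(cnt[occ] / max(cnt))
  mids <- function(b) (b[-1] + b[-length(b)]) / 2
  grid <- tibble::tibble(
    ix = rep(seq_len(bins), bins), iy = rep(seq_len(bins), each = bins),
    rmsd = rep(mids(bx), bins), dipole = rep(mids(by), each = bins),
    count = as.vector(cnt), free_energy = as.vector(fmat)
  )
  basins <- find_basins(fmat, cnt, mids(bx), mids(by))
  keep <- basins$population >= min_population
  if (any(keep)) basins <- basins[keep, ]
  basins$basin <- seq_len(nrow(basins))
  structure(list(grid = grid, basins = basins, coords = xy,
                 temperature = temperature, kt = kt,
                 breaks = list(rmsd = bx, dipole = by)),
            class = "ma_fes")
}

# local minima of F with steepest-descent basin assignment
find_basins <- function(fmat, cnt, xm, ym) {
  nb <- nrow(fmat)
  occ <- which(!is.na(fmat), arr.ind = TRUE)
  nbhd <- function(i, j) {
    di <- rep(-1:1, 3); dj <- rep(-1:1, each = 3)
    keep <- !(di == 0 & dj == 0)
    ii <- i + di[keep]; jj <- j + dj[keep]
    ok <- ii >= 1 & ii <= nb & jj >= 1 & jj <= nb
    cbind(ii[ok], jj[ok])
  }
  # steepest-descent target of each occupied cell
  descend <- function(i, j) {
    repeat {
      nbs <- nbhd(i, j)
      fv <- fmat[nbs]
      fv[is.na(fv)] <- Inf
      if (all(fv >= fmat[i, j])) return(c(i, j))
      k <- which.min(fv)
      i <- nbs[k, 1]; j <- nbs[k, 2]
    }
  }
  targets <- t(apply(occ, 1, function(rc) descend(rc[1], rc[2])))
  key <- paste(targets[, 1], targets[, 2])
  uniq <- !duplicated(key)
  mins <- targets[uniq, , drop = FALSE]
  pop <- tapply(cnt[occ], key, sum)[paste(mins[, 1], mins[, 2])]
  ord <- order(fmat[mins])
  tibble::tibble(
    basin = seq_len(nrow(mins)),
    rmsd = xm[mins[ord, 1]], dipole = ym[mins[ord, 2]],
    free_energy = fmat[mins][ord],
    population = as.numeric(pop[ord]) / sum(cnt)
  )
}

#' @export
print.ma_fes <- function(x, ...) {
  cat("<ma_fes> ", nrow(x$coords), " frames, ",
      sum(x$grid$count > 0), " occupied bins, ", nrow(x$basins),
      " basin(s); T = ", x$temperature, " K\n", sep = "")
  invisible(x)
}

# helical window + run-length criterion (coarse DSSP substitute)
HELIX_PHI <- c(-100, -30)
HELIX_PSI <- c(-77, -17)

helical_matrix <- function(ens, min_run = 4) {
  inw <- ens$phi >= HELIX_PHI[1] & ens$phi <= HELIX_PHI[2] &
    ens$psi >= HELIX_PSI[1] & ens$psi <= HELIX_PSI[2]
  inw[is.na(inw)] <- FALSE
  t(apply(inw, 1, function(row) {
    r <- rle(row)
    r$values <- r$values & r$lengths >= min_run
    inverse.rle(r)
  }))
}

#' Per-residue helix population
#'
#' A residue counts as helical in a frame iff its (phi, psi) falls in the
#' helical window (phi in \[-100, -30\], psi in \[-77, -17\]) and it belongs
#' to a run of at least `min_run` consecutive in-window residues — a
#' dihedral-based substitute for an H-bond secondary-structure assignment,
#' which the coarse model cannot support.
#'
#' @param ens An `ma_ensemble`.
#' @param min_run Minimum helical run length.
#' @return Tibble: `residue`, `aa`, `helix_fraction`.
#' @export
helix_population <- function(ens, min_run = 4) {
  h <- helical_matrix(ens, min_run)
  tibble::tibble(residue = seq_len(ens$chain$n), aa = ens$chain$residues$aa,
                 helix_fraction = colMeans(h))
}

#' Per-residue Calpha RMSF
#'
#' Frames are least-squares superposed on the mean structure (CA atoms of the
#' range; two refinement passes), then
#' `RMSF_i = sqrt(mean |r_i - <r_i>|^2)`.
#'
#' @param ens An `ma_ensemble` with >= 2 frames.
#' @param residues Residue range (default: whole chain).
#' @return Tibble: `residue`, `aa`, `rmsf` (Angstrom).
#' @export
rmsf <- function(ens, residues = seq_len(ens$chain$n)) {
  if (n_frames(ens) < 2) abort("Need >= 2 frames for RMSF.")
  residues <- default_range(ens$chain, residues)
  rows <- atom_row(residues, "CA")
  ca <- lapply(seq_len(n_frames(ens)), function(f) ens$coords[rows, , f])
  ref <- ca[[1]]
  for (pass in 1:3) {
    ca <- lapply(ca, function(P) apply_kabsch(P, kabsch(P, ref)))
    ref <- Reduce(`+`, ca) / length(ca)
  }
  dev <- sapply(ca, function(P) rowSums((P - ref)^2))
  tibble::tibble(residue = residues,
                 aa = ens$chain$residues$aa[residues],
                 rmsf = sqrt(rowMeans(dev)))
}

# sidechain-centroid (charged-group / hydrophobic-group) positions; the
# N-terminal amine group is represented by the backbone N of residue 1
group_position_rows <- function(chain, residues, nterm_as_n = TRUE) {
  rows <- atom_row(residues, "SC")
  if (nterm_as_n) rows[residues == 1L] <- atom_row(1L, "N")
  rows
}

contact_occupancy <- function(ens, pairs, cutoff, nterm_as_n) {
  if (nrow(pairs) == 0) {
    return(tibble::tibble(res_i = integer(), res_j = integer(),
                          occupancy = numeric()))
  }
  ri <- group_position_rows(ens$chain, pairs$res_i, nterm_as_n)
  rj <- group_position_rows(ens$chain, pairs$res_j, nterm_as_n)
  hits <- rep(0, nrow(pairs))
  for (f in seq_len(n_frames(ens))) {
    X <- ens$coords[, , f]
    d2 <- rowSums((X[ri, , drop = FALSE] - X[rj, , drop = FALSE])^2)
    hits <- hits + (d2 <= cutoff^2)
  }
  dplyr::mutate(pairs, occupancy = hits / n_frames(ens))
}

pair_label <- function(chain, i, j) {
  paste0(chain$residues$aa[i], i, "/", chain$residues$aa[j], j)
}

#' Salt-bridge occupancy map
#'
#' Fraction of frames in which the charged-group centres of a
#' (positive, negative) residue pair lie within `cutoff` (default 5.0
#' Angstrom). In the coarse model the charged-group centre of mass is the
#' sidechain centroid; the N-terminal amine uses the backbone N of residue 1.
#' Only pairs with |i - j| >= 2 are reported. The result is symmetric by
#' construction (each unordered pair appears once).
#'
#' @param ens An `ma_ensemble`.
#' @param cutoff Distance cutoff, Angstrom.
#' @return A `ma_contact_map` tibble: `res_i`, `res_j`, `pair`, `type`,
#'   `occupancy`.
#' @export
salt_bridge_occupancy <- function(ens, cutoff = 5.0) {
  res <- ens$chain$residues
  pos <- res$residue[res$charge_class == "positive"]
  neg <- res$residue[res$charge_class == "negative"]
  if (length(pos) == 0 || length(neg) == 0) {
    abort("Chain needs at least one positive and one negative residue.")
  }
  pairs <- tidyr::expand_grid(res_i = pos, res_j = neg) |>
    dplyr::filter(abs(.data$res_i - .data$res_j) >= 2)
  out <- contact_occupancy(ens, pairs, cutoff, nterm_as_n = TRUE) |>
    dplyr::mutate(pair = pair_label(ens$chain, .data$res_i, .data$res_j),
                  type = "salt-bridge", .after = "res_j")
  class(out) <- c("ma_contact_map", class(out))
  out
}

#' Hydrophobic contact map
#'
#' Occupancy of sidechain-centroid contacts (cutoff 5.0 Angstrom) over all
#' hydrophobic residue pairs with |i - j| >= 2.
#'
#' @inheritParams salt_bridge_occupancy
#' @return A `ma_contact_map` tibble.
#' @export
hydrophobic_contact_map <- function(ens, cutoff = 5.0) {
  res <- ens$chain$residues
  hyd <- res$residue[res$hydro_class == "hydrophobic"]
  pairs <- tidyr::expand_grid(res_i = hyd, res_j = hyd) |>
    dplyr::filter(.data$res_j - .data$res_i >= 2)
  out <- contact_occupancy(ens, pairs, cutoff, nterm_as_n = FALSE) |>
    dplyr::mutate(pair = pair_label(ens$chain, .data$res_i, .data$res_j),
                  type = "hydrophobic", .after = "res_j")
  class(out) <- c("ma_contact_map", class(out))
  out
}
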