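# Coarse bilayer model and bilayer-relative geometry/energetics: surface
# fitting, helix tilt, insertion depths, sidechain-lipid contacts, 12-6 +
# Coulomb interaction energies, and PRE attenuation for doxyl labels.

LIPID_SPECIES <- c("DOPE", "DOPS", "DOPC")
LIPID_RES3 <- c(DOPE = "DPE", DOPS = "DPS", DOPC = "DPC")

# mean |z| (Angstrom from the midplane) of headgroup P, glycerol and chain
# carbons 1..18; piecewise linear through the documented anchor depths
# (C5 = 12.5, C10 = 7.5, C16 = 2.5), strictly decreasing with carbon index.
lipid_z_profile <- function() {
  carbons <- stats::approx(x = c(1, 5, 10, 16, 18),
                           y = c(15.5, 12.5, 7.5, 2.5, 1.5),
                           xout = 1:18)$y
  c(P = 19, GL = 16.5, setNames(carbons, sprintf("C%02d", 1:18)))
}

#' Build a coarse two-leaflet bilayer patch
#'
#' Lipids (1 headgroup P site, 1 glycerol site, 18 chain-carbon sites) sit on
#' a jittered lattice split evenly across the two leaflets; species are
#' assigned to match the requested molar ratio within rounding (largest
#' remainder). A `label_fraction` of lipids (default 2 percent, at least one
#' when a label is requested) is marked as carrying a doxyl spin label; the
#' probed carbon is chosen in [pre_attenuation()].
#'
#' @param n_lipids Total lipid count (>= 8, even).
#' @param ratio Molar ratio DOPE:DOPS:DOPC (default 5:3:2).
#' @param seed RNG seed (deterministic per seed).
#' @param label `"none"`, `"C5"`, `"C10"`, `"C16"` or `"headgroup"`: default
#'   doxyl position recorded on the labelled lipids.
#' @param label_fraction Fraction of lipids doped with the label.
#' @param spacing Lattice spacing, Angstrom (~area per lipid = spacing^2).
#' @return An object of class `ma_bilayer`: `lipids`, `sites`, `box`,
#'   `z_profile`.
#' @export
build_bilayer <- function(n_lipids, ratio = c(5, 3, 2), seed = 1,
                          label = "none", label_fraction = 0.02,
                          spacing = 8) {
  stopifnot(n_lipids >= 8, n_lipids %% 2 == 0, length(ratio) == 3,
            all(ratio > 0))
  with_seed(seed, {
  # largest-remainder apportionment of species counts
  q <- n_lipids * ratio / sum(ratio)
  cnt <- floor(q)
  rem <- n_lipids - sum(cnt)
  if (rem > 0) {
    add <- order(q - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[add] <- cnt[add] + 1
  }
  species <- sample(rep(LIPID_SPECIES, cnt))
  per_leaf <- n_lipids / 2
  side <- ceiling(sqrt(per_leaf))
  lx <- side * spacing
  gx <- ((seq_len(per_leaf) - 1) %% side + 0.5) * spacing
  gy <- ((seq_len(per_leaf) - 1) %/% side + 0.5) * spacing
  zprof <- lipid_z_profile()
  n_lab <- if (label == "none") round(label_fraction * n_lipids) else
    max(1, round(label_fraction * n_lipids))
  labelled <- sample(n_lipids, n_lab)
  lipids <- tibble::tibble(
    lipid = seq_len(n_lipids),
    species = species,
    leaflet = rep(c("upper", "lower"), each = per_leaf),
    x = rep(gx, 2) + rnorm(n_lipids, 0, 0.8),
    y = rep(gy, 2) + rnorm(n_lipids, 0, 0.8),
    labelled = seq_len(n_lipids) %in% labelled,
    label = ifelse(seq_len(n_lipids) %in% labelled & label != "none",
                   label, NA_character_)
  )
  sgn <- ifelse(lipids$leaflet == "upper", 1, -1)
  sites <- purrr::map_dfr(seq_len(n_lipids), function(l) {
    tibble::tibble(
      lipid = l, species = lipids$species[l], leaflet = lipids$leaflet[l],
      site = names(zprof),
      x = lipids$x[l] + c(0, 0, rnorm(18, 0, 0.5)),
      y = lipids$y[l] + c(0, 0, rnorm(18, 0, 0.5)),
      z = sgn[l] * (zprof + rnorm(20, 0, 0.3))
    )
  })
  structure(list(lipids = lipids, sites = sites,
                 box = c(x = lx, y = lx), z_profile = zprof,
                 composition = setNames(as.integer(cnt), LIPID_SPECIES)),
            class = "ma_bilayer")
  })
}

#' @export
print.ma_bilayer <- function(x, ...) {
  cat("<ma_bilayer> ", nrow(x$lipids), " lipids (",
      paste(names(x$composition), x$composition, collapse = ", "),
      "), box ", round(x$box[1]), " x ", round(x$box[2]), " A, ",
      sum(x$lipids$labelled), " labelled\n", sep = "")
  invisible(x)
}

# evaluate code with a temporary RNG state, leaving the caller's untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Write / read a bilayer as PDB
#'
#' Lipids as residues DPE/DPS/DPC with atoms P, GL, C01..C18; labelled lipids
#' carry a B-factor of 1 on the P atom. Leaflet is the chain id (U/L).
#'
#' @param bilayer An `ma_bilayer`.
#' @param path File path.
#' @return `read_bilayer_pdb()` returns an `ma_bilayer`.
#' @export
write_bilayer_pdb <- function(bilayer, path) {
  s <- bilayer$sites
  lab <- bilayer$lipids$labelled[s$lipid]
  lines <- sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00%6.2f",
                   seq_len(nrow(s)), s$site, LIPID_RES3[s$species],
                   ifelse(s$leaflet == "upper", "U", "L"), s$lipid,
                   s$x, s$y, s$z,
                   ifelse(s$site == "P" & lab, 1, 0))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' @rdname write_bilayer_pdb
#' @export
read_bilayer_pdb <- function(path) {
  txt <- readLines(path)
  atom <- txt[startsWith(txt, "ATOM  ") | startsWith(txt, "HETATM")]
  site <- trimws(substr(atom, 13, 16))
  res3 <- trimws(substr(atom, 18, 20))
  chainid <- substr(atom, 22, 22)
  lipid <- as.integer(substr(atom, 23, 26))
  x <- as.numeric(substr(atom, 31, 38))
  y <- as.numeric(substr(atom, 39, 46))
  z <- as.numeric(substr(atom, 47, 54))
  bf <- as.numeric(substr(atom, 61, 66))
  species <- names(LIPID_RES3)[match(res3, LIPID_RES3)]
  leaflet <- ifelse(chainid == "U", "upper", "lower")
  sites <- tibble::tibble(lipid = lipid, species = species, leaflet = leaflet,
                          site = site, x = x, y = y, z = z)
  hp <- sites[sites$site == "P", ]
  lab <- lipid[site == "P"][bf[site == "P"] > 0.5]
  lipids <- tibble::tibble(lipid = hp$lipid, species = hp$species,
                           leaflet = hp$leaflet, x = hp$x, y = hp$y,
                           labelled = hp$lipid %in% lab,
                           label = NA_character_)
  cnt <- table(factor(lipids$species, levels = LIPID_SPECIES))
  structure(list(lipids = lipids, sites = sites,
                 box = c(x = max(x) - min(x), y = max(y) - min(y)),
                 z_profile = lipid_z_profile(),
                 composition = setNames(as.integer(cnt), LIPID_SPECIES)),
            class = "ma_bilayer")
}

#' Fit the local membrane surface
#'
#' Least-squares plane through the headgroup phosphorus atoms that lie
#' within `radius` of any protein atom, on the leaflet proximal to the
#' protein; the midplane comes from the mean P height of both leaflets. The
#' unit normal points from the midplane toward the protein.
#'
#' @param bilayer An `ma_bilayer`.
#' @param conf An `ma_conformation` (positioned relative to the bilayer).
#' @param radius Qualification radius for P atoms, Angstrom.
#' @return An object of class `ma_membrane_frame`: `normal`, `point`,
#'   `midplane_z`, `residual`, `n_points`.
#' @export
fit_membrane_surface <- function(bilayer, conf, radius = 10) {
  p <- dplyr::filter(bilayer$sites, .data$site == "P")
  prot <- conf$coords
  pm <- as.matrix(p[, c("x", "y", "z")])
  # min distance of each P to any protein atom
  d2min <- vapply(seq_len(nrow(pm)), function(i) {
    min(colSums((t(prot) - pm[i, ])^2))
  }, numeric(1))
  qual <- d2min <= radius^2
  if (sum(qual) < 3) {
    abort(sprintf(
      "Fewer than 3 phosphorus atoms within %g A of the protein.", radius))
  }
  leafs <- p$leaflet[qual]
  prox <- names(which.max(table(leafs)))
  sel <- qual & p$leaflet == prox
  if (sum(sel) < 3) {
    abort(sprintf(
      "Fewer than 3 phosphorus atoms within %g A of the protein.", radius))
  }
  fit <- lm(z ~ x + y, data = p[sel, ])
  b <- coef(fit)
  nrm <- c(-b["x"], -b["y"], 1)
  nrm <- nrm / sqrt(sum(nrm^2))
  midplane_z <- mean(c(mean(p$z[p$leaflet == "upper"]),
                       mean(p$z[p$leaflet == "lower"])))
  # orient toward the protein
  centre <- colMeans(prot)
  if (sum(nrm * (centre - c(0, 0, midplane_z))) < 0) nrm <- -nrm
  structure(list(normal = unname(nrm),
                 point = c(mean(p$x[sel]), mean(p$y[sel]),
                           mean(stats::fitted(fit))),
                 midplane_z = midplane_z,
                 residual = sqrt(mean(stats::residuals(fit)^2)),
                 n_points = sum(sel)),
            class = "ma_membrane_frame")
}

#' @export
print.ma_membrane_frame <- function(x, ...) {
  cat("<ma_membrane_frame> normal (", paste(round(x$normal, 3), collapse = ", "),
      "), midplane z = ", round(x$midplane_z, 2), " A, fit on ", x$n_points,
      " P atoms (rms ", round(x$residual, 2), " A)\n", sep = "")
  invisible(x)
}

# principal axis of the CA trace, oriented N -> C
helix_axis <- function(conf, residues) {
  ca <- site_coords(conf, "CA", residues)
  pc <- prcomp(ca)
  if (pc$sdev[1] < 2 * pc$sdev[2]) {
    abort("Degenerate helix axis: the CA trace is not elongated enough.")
  }
  v <- pc$rotation[, 1]
  if (sum(v * (ca[nrow(ca), ] - ca[1, ])) < 0) v <- -v
  list(axis = v, centre = colMeans(ca),
       residual = sqrt(mean(pc$sdev[2:3]^2)))
}

#' Helix tilt angle relative to the membrane surface
#'
#' Angle between the helix axis (first principal component of the CA trace,
#' oriented N to C) and its projection on the fitted membrane plane.
#' Positive when the N-terminal end is the deeper one; range \[-90, 90\]
#' degrees.
#'
#' @param conf An `ma_conformation`.
#' @param frame An `ma_membrane_frame`.
#' @param residues Residue range defining the axis (default 6-25).
#' @return Tilt in degrees.
#' @export
helix_tilt_angle <- function(conf, frame, residues = NULL) {
  residues <- default_range(conf$chain, residues)
  ax <- helix_axis(conf, residues)
  s <- sum(ax$axis * frame$normal)
  alpha <- acos(pmin(1, pmax(-1, s))) * 180 / pi
  90 - alpha
}

#' Per-residue insertion depth
#'
#' Signed distance of the sidechain centroid (backbone CA for glycine, whose
#' centroid is coincident) from the bilayer midplane along the membrane
#' normal, positive toward the proximal leaflet surface; mean and SD over
#' frames. The membrane frame is fitted per conformation.
#'
#' @param ens An `ma_ensemble` positioned relative to the bilayer.
#' @param bilayer An `ma_bilayer`.
#' @return Tibble: `residue`, `aa`, `mean_depth`, `sd_depth` (Angstrom).
#' @export
residue_depths <- function(ens, bilayer) {
  n <- ens$chain$n
  rows <- atom_row(seq_len(n), "SC")
  depths <- vapply(seq_len(n_frames(ens)), function(f) {
    cf <- ensemble_conformation(ens, f)
    frame <- fit_membrane_surface(bilayer, cf)
    X <- cf$coords[rows, , drop = FALSE]
    rel <- sweep(X, 2, c(0, 0, frame$midplane_z))
    as.vector(rel %*% frame$normal)
  }, numeric(n))
  depths <- matrix(depths, nrow = n)
  tibble::tibble(residue = seq_len(n), aa = ens$chain$residues$aa,
                 mean_depth = rowMeans(depths),
                 sd_depth = apply(depths, 1, sd))
}

#' Mean sidechain-lipid contact counts
#'
#' Number of lipid sites within `cutoff` (default 5.0 Angstrom) of each
#' residue's sidechain centroid, averaged over frames.
#'
#' @param ens An `ma_ensemble`.
#' @param bilayer An `ma_bilayer`.
#' @param cutoff Contact cutoff, Angstrom.
#' @return Tibble: `residue`, `aa`, `contacts`.
#' @export
sidechain_lipid_contacts <- function(ens, bilayer, cutoff = 5.0) {
  n <- ens$chain$n
  rows <- atom_row(seq_len(n), "SC")
  L <- as.matrix(bilayer$sites[, c("x", "y", "z")])
  counts <- matrix(0, n, n_frames(ens))
  for (f in seq_len(n_frames(ens))) {
    X <- ens$coords[rows, , f]
    for (i in seq_len(n)) {
      d2 <- (L[, 1] - X[i, 1])^2 + (L[, 2] - X[i, 2])^2 + (L[, 3] - X[i, 3])^2
      counts[i, f] <- sum(d2 <= cutoff^2)
    }
  }
  tibble::tibble(residue = seq_len(n), aa = ens$chain$residues$aa,
                 contacts = rowMeans(counts))
}

#' 12-6 Lennard-Jones pair energy
#'
#' `4 eps ((sigma/r)^12 - (sigma/r)^6)`; zero at r = sigma, minimum -eps
#' at r = 2^(1/6) sigma.
#'
#' @param r Distance (same units as sigma).
#' @param sigma,eps LJ parameters.
#' @return Energy in the units of `eps`.
#' @export
lj_energy <- function(r, sigma, eps) {
  sr6 <- (sigma / r)^6
  4 * eps * (sr6^2 - sr6)
}

COULOMB_F <- 138.935458 # kJ nm / (mol e^2)

#' Coulomb pair energy
#'
#' `f q1 q2 / r` with the electrostatic conversion constant
#' f = 138.935 kJ nm / (mol e^2).
#'
#' @param r_nm Distance in nm.
#' @param q1,q2 Charges in e.
#' @return Energy in kJ/mol.
#' @export
coulomb_energy <- function(r_nm, q1, q2) {
  COULOMB_F * q1 * q2 / r_nm
}

#' Sidechain-lipid interaction parameters
#'
#' Default LJ parameters per (protein class, lipid site type) and the charge
#' assignments: protein formal charges, DOPS headgroup -1 e, other lipid
#' sites neutral. Combination: `sigma_ij = (sigma_i + sigma_j) / 2`.
#'
#' @param sigma_lipid Named LJ sigma per lipid site class (P, GL, C),
#'   Angstrom.
#' @param sigma_protein Named sigma per protein class, Angstrom.
#' @param eps Matrix of well depths (kJ/mol), rows = protein class
#'   (hydrophobic, other), columns = lipid site class (P, GL, C).
#' @return Parameter list for [interaction_energies()].
#' @export
lipid_interaction_params <- function(
    sigma_lipid = c(P = 4.2, GL = 4.0, C = 4.0),
    sigma_protein = c(hydrophobic = 4.6, other = 4.2),
    eps = matrix(c(0.15, 0.50, 0.20, 0.40, 0.80, 0.20),
                 nrow = 2, dimnames = list(c("hydrophobic", "other"),
                                           c("P", "GL", "C")))) {
  list(sigma_lipid = sigma_lipid, sigma_protein = sigma_protein, eps = eps,
       dops_charge = -1, coulomb_f = COULOMB_F)
}

lipid_site_class <- function(site) {
  ifelse(site == "P", "P", ifelse(site == "GL", "GL", "C"))
}

#' Per-residue sidechain-lipid interaction energies
#'
#' Frame-averaged 12-6 Lennard-Jones and Coulomb sums between each residue's
#' sidechain centroid (plus the charged N-terminal amine on the backbone N of
#' residue 1 for the Coulomb term) and all lipid sites within the interaction
#' cutoff (default 0.9 nm).
#'
#' Distances are floored at `0.9 sigma_ij` before evaluating the pair terms:
#' constructed placements are not energy-minimised, and the floor keeps the
#' r^-12 singularity from dominating frame averages while preserving the
#' attractive region unchanged.
#'
#' @param ens An `ma_ensemble`.
#' @param bilayer An `ma_bilayer`.
#' @param params See [lipid_interaction_params()].
#' @param cutoff_nm Interaction cutoff, nm.
#' @return Tibble: `residue`, `aa`, `e_vdw`, `e_coul` (kJ/mol).
#' @export
interaction_energies <- function(ens, bilayer,
                                 params = lipid_interaction_params(),
                                 cutoff_nm = 0.9) {
  n <- ens$chain$n
  res <- ens$chain$residues
  cut <- cutoff_nm * 10
  L <- as.matrix(bilayer$sites[, c("x", "y", "z")])
  lclass <- lipid_site_class(bilayer$sites$site)
  lq <- ifelse(bilayer$sites$species == "DOPS" & bilayer$sites$site == "P",
               params$dops_charge, 0)
  pclass <- ifelse(res$hydro_class == "hydrophobic", "hydrophobic", "other")
  sig_p <- params$sigma_protein[pclass]
  sig_ij <- outer(sig_p, params$sigma_lipid[lclass], `+`) / 2 # n x sites
  eps_ij <- params$eps[cbind(rep(pclass, length(lclass)),
                             rep(lclass, each = n))]
  eps_ij <- matrix(eps_ij, nrow = n)
  rows <- atom_row(seq_len(n), "SC")
  nrow1 <- atom_row(1L, "N")
  evdw <- ecoul <- matrix(0, n, n_frames(ens))
  for (f in seq_len(n_frames(ens))) {
    X <- ens$coords[rows, , f]
    d <- sqrt(pmax(outer(rowSums(X^2), rowSums(L^2), `+`) - 2 * X %*% t(L), 0))
    within <- d <= cut
    lj <- lj_energy(pmax(d, 0.9 * sig_ij), sig_ij, eps_ij)
    lj[!within] <- 0
    evdw[, f] <- rowSums(lj)
    # Coulomb: charged sidechains against DOPS headgroups
    qi <- res$sc_charge
    cl <- outer(qi, lq) * COULOMB_F * 10 / pmax(d, 2)
    cl[!within | !is.finite(cl)] <- 0
    ecoul[, f] <- rowSums(cl)
    # N-terminal amine
    Xn <- ens$coords[nrow1, , f]
    dn <- sqrt(colSums((t(L) - Xn)^2))
    seln <- dn <= cut & lq != 0
    ecoul[1, f] <- ecoul[1, f] +
      sum(COULOMB_F * 1 * lq[seln] * 10 / pmax(dn[seln], 2))
  }
  tibble::tibble(residue = seq_len(n), aa = res$aa,
                 e_vdw = rowMeans(evdw), e_coul = rowMeans(ecoul))
}

#' PRE attenuation profile for a doxyl-labelled bilayer
#'
#' For each residue, the effective distance to the label ensemble is
#' `r_eff = <min_labels r^-6>_frames^(-1/6)` (sidechain centroid to the doxyl
#' site of each labelled lipid at the chosen carbon, or the headgroup P).
#' The attenuation `A = 1 / (1 + (r_eff / R_c)^-6)` runs from 0 (fully
#' broadened, label much closer than `R_c`) to 1 (unaffected); residues with
#' `A < 0.5` are flagged broadened. An effective-distance sigmoid is used
#' rather than full relaxation theory (correlation times are outside the
#' coarse model).
#'
#' @param ens An `ma_ensemble`.
#' @param bilayer An `ma_bilayer` with labelled lipids.
#' @param label `"C5"`, `"C10"`, `"C16"` or `"headgroup"`.
#' @param r_c Half-attenuation distance, Angstrom.
#' @return A `ma_pre_profile` tibble: `residue`, `aa`, `r_eff`,
#'   `attenuation`, `broadened`.
#' @export
pre_attenuation <- function(ens, bilayer, label = c("C5", "C10", "C16",
                                                    "headgroup"),
                            r_c = 13) {
  label <- match.arg(label)
  site_name <- if (label == "headgroup") "P" else
    sprintf("C%02d", as.integer(sub("C", "", label)))
  lab_lipids <- bilayer$lipids$lipid[bilayer$lipids$labelled]
  if (length(lab_lipids) == 0) abort("Bilayer has no labelled lipids.")
  Ls <- dplyr::filter(bilayer$sites, .data$lipid %in% lab_lipids,
                      .data$site == site_name)
  L <- as.matrix(Ls[, c("x", "y", "z")])
  n <- ens$chain$n
  rows <- atom_row(seq_len(n), "SC")
  inv6 <- matrix(0, n, n_frames(ens))
  for (f in seq_len(n_frames(ens))) {
    X <- ens$coords[rows, , f]
    for (i in seq_len(n)) {
      d2 <- (L[, 1] - X[i, 1])^2 + (L[, 2] - X[i, 2])^2 + (L[, 3] - X[i, 3])^2
      inv6[i, f] <- min(d2)^-3
    }
  }
  r_eff <- rowMeans(inv6)^(-1 / 6)
  a <- 1 / (1 + (r_eff / r_c)^-6)
  out <- tibble::tibble(residue = seq_len(n), aa = ens$chain$residues$aa,
                        r_eff = r_eff, attenuation = a, broadened = a < 0.5)
  class(out) <- c("ma_pre_profile", class(out))
  attr(out, "label") <- label
  out
}
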