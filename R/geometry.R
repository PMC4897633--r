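# Conformation container and scalar descriptors. Coordinates are Angstrom,
# torsions degrees; atoms are ordered N, CA, C, O, SC within each residue.

ATOM_NAMES <- c("N", "CA", "C", "O", "SC")

atom_row <- function(residue, atom) {
  5L * (residue - 1L) + match(atom, ATOM_NAMES)
}

#' Low-level conformation constructor
#'
#' Wraps coordinates and torsions without validation or re-extraction; used
#' when coordinates are edited directly (placements, planted constructions)
#' and the torsions are already known.
#'
#' @param chain An [peptide_chain()].
#' @param coords Numeric matrix `5 * chain$n` x 3.
#' @param phi,psi Torsions, degrees.
#' @return An `ma_conformation`.
#' @export
new_conformation <- function(chain, coords, phi, psi) {
  structure(list(chain = chain, coords = coords, phi = phi, psi = psi),
            class = "ma_conformation")
}

#' Build a conformation from backbone torsions
#'
#' Places atoms by sequential internal-coordinate (NeRF) construction with
#' fixed bond lengths/angles and omega = 180 degrees. `phi[1]` is a gauge
#' freedom (there is no preceding carbonyl); it is used in the build and
#' carried in the object so the torsion round trip is exact.
#'
#' @param chain An [peptide_chain()].
#' @param phi,psi Numeric vectors of length `chain$n`, degrees.
#' @return An `ma_conformation`: coordinates plus torsions.
#' @export
torsions_to_conformation <- function(chain, phi, psi) {
  if (length(phi) != chain$n || length(psi) != chain$n) {
    abort("One (phi, psi) pair per residue is required.")
  }
  coords <- cpp_build_coords(as.double(phi), as.double(psi),
                             chain$residues$sc_dist)
  new_conformation(chain, coords, as.double(phi), as.double(psi))
}

#' Construct a conformation from raw coordinates
#'
#' Torsions are extracted from the coordinates; `phi[1]` cannot be recovered
#' from atoms and defaults to `phi1`.
#'
#' @param chain An [peptide_chain()].
#' @param coords Numeric matrix `5 * chain$n` x 3 (N, CA, C, O, SC per residue).
#' @param phi1 Gauge value for the first phi (degrees).
#' @return An `ma_conformation`.
#' @export
conformation_from_coords <- function(chain, coords, phi1 = -57) {
  stopifnot(is.matrix(coords), nrow(coords) == 5 * chain$n, ncol(coords) == 3)
  tor <- cpp_extract_torsions(coords)
  tor$phi[1] <- phi1
  new_conformation(chain, coords, tor$phi, tor$psi)
}

#' @export
print.ma_conformation <- function(x, ...) {
  cat("<ma_conformation> ", x$chain$n, " residues, ",
      nrow(x$coords), " sites\n", sep = "")
  invisible(x)
}

#' Atom table of a conformation
#'
#' @param conf An `ma_conformation`.
#' @return Tibble with columns `residue`, `aa`, `atom`, `x`, `y`, `z`.
#' @export
conformation_atoms <- function(conf) {
  n <- conf$chain$n
  tibble::tibble(
    residue = rep(seq_len(n), each = 5L),
    aa = rep(conf$chain$residues$aa, each = 5L),
    atom = rep(ATOM_NAMES, n),
    x = conf$coords[, 1], y = conf$coords[, 2], z = conf$coords[, 3]
  )
}

#' Torsion table of a conformation
#'
#' @param conf An `ma_conformation`.
#' @return Tibble with columns `residue`, `phi`, `psi` (degrees).
#' @export
conformation_torsions <- function(conf) {
  tibble::tibble(residue = seq_len(conf$chain$n), phi = conf$phi,
                 psi = conf$psi)
}

#' Ideal alpha-helix conformation
#'
#' All residues at (phi, psi) = (-57, -47) degrees, the package's numerical
#' definition of an ideal helix.
#'
#' @param chain An [peptide_chain()] with at least 4 residues.
#' @return An `ma_conformation`.
#' @export
build_ideal_helix <- function(chain) {
  if (chain$n < 4) abort("Chain too short for a helix (need >= 4 residues).")
  torsions_to_conformation(chain, rep(-57, chain$n), rep(-47, chain$n))
}

# coordinates of one site type over a residue range
site_coords <- function(conf, atom = "CA", residues = NULL) {
  residues <- default_range(conf$chain, residues)
  conf$coords[atom_row(residues, atom), , drop = FALSE]
}

# Kabsch least-squares superposition: rotation R and translations such that
# R %*% (P - cP) + cQ approximates Q
kabsch <- function(P, Q) {
  cP <- colMeans(P); cQ <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cP), sweep(Q, 2, cQ))
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  list(R = R, cP = cP, cQ = cQ)
}

apply_kabsch <- function(X, k) {
  sweep(sweep(X, 2, k$cP) %*% t(k$R), 2, k$cQ, "+")
}

#' Optimal-superposition Calpha RMSD
#'
#' Least-squares rigid-body fit on the CA atoms of `residues` only, then RMSD
#' over those same atoms. Default range is the assigned region 6-25 (the
#' whole chain when shorter than 25 residues).
#'
#' @param conf,ref `ma_conformation` objects sharing a chain length.
#' @param residues Residue indices (default 6-25).
#' @return RMSD in Angstrom.
#' @export
rmsd_ca <- function(conf, ref, residues = NULL) {
  residues <- default_range(conf$chain, residues)
  if (length(residues) < 3) abort("Need at least 3 residues for superposition.")
  P <- site_coords(conf, "CA", residues)
  Q <- site_coords(ref, "CA", residues)
  P2 <- apply_kabsch(P, kabsch(P, Q))
  sqrt(mean(rowSums((P2 - Q)^2)))
}

#' Formal charge table of a conformation
#'
#' Formal charges (+1/-1 e) on charged sidechain centroids plus the
#' N-terminal amine (+1 on the backbone N of residue 1). Backbone partial
#' dipoles are not included by default.
#'
#' @param chain An [peptide_chain()].
#' @return Tibble with columns `residue`, `atom`, `q` for nonzero charges.
#' @export
formal_charges <- function(chain) {
  sc <- tibble::tibble(residue = chain$residues$residue, atom = "SC",
                       q = chain$residues$sc_charge)
  nt <- tibble::tibble(residue = 1L, atom = "N", q = chain$nterm_charge)
  dplyr::bind_rows(nt, sc) |> dplyr::filter(.data$q != 0)
}

#' Dipole moment of a residue selection
#'
#' Magnitude of `sum(q_i (r_i - origin))` in e nm (coordinates are Angstrom
#' internally; 1 nm = 10 Angstrom). The default origin is the centre of mass
#' (unit masses over all sites) of the selected residues; since the selection
#' need not be net-neutral the origin matters and is configurable.
#'
#' @param conf An `ma_conformation`.
#' @param residues Residue selection (default 6-25).
#' @param charges Charge table as in [formal_charges()]; default formal
#'   charges. Charges on residues outside the selection are ignored.
#' @param origin `"com"`, `"zero"`, or a length-3 numeric (Angstrom).
#' @return Dipole magnitude in e nm.
#' @export
dipole_moment <- function(conf, residues = NULL, charges = NULL,
                          origin = "com") {
  residues <- default_range(conf$chain, residues)
  if (is.null(charges)) charges <- formal_charges(conf$chain)
  if (any(is.na(charges$q))) abort("Missing charges.")
  charges <- dplyr::filter(charges, .data$residue %in% residues)
  o <- if (is.numeric(origin)) {
    origin
  } else if (identical(origin, "zero")) {
    c(0, 0, 0)
  } else {
    rows <- as.vector(vapply(residues, function(r) atom_row(rep(r, 5), ATOM_NAMES),
                             integer(5)))
    colMeans(conf$coords[rows, , drop = FALSE])
  }
  if (nrow(charges) == 0) return(0)
  pos <- conf$coords[atom_row(charges$residue, charges$atom), , drop = FALSE]
  mu <- colSums(charges$q * sweep(pos, 2, o))
  sqrt(sum(mu^2)) / 10
}

#' Radius of gyration
#'
#' Root-mean-square distance of sites to their centroid, unit masses.
#'
#' @param x An `ma_conformation` or a numeric coordinate matrix.
#' @param ... Unused.
#' @return Rg in the units of the coordinates (Angstrom for conformations).
#' @export
radius_of_gyration <- function(x, ...) UseMethod("radius_of_gyration")

#' @export
radius_of_gyration.matrix <- function(x, ...) {
  sqrt(mean(rowSums(sweep(x, 2, colMeans(x))^2)))
}

#' @export
radius_of_gyration.ma_conformation <- function(x, ...) {
  radius_of_gyration(x$coords)
}

# deterministic golden-spiral unit sphere points
fibonacci_sphere <- function(n) {
  i <- seq(0, n - 1)
  z <- 1 - 2 * (i + 0.5) / n
  th <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(th), r * sin(th), z)
}

SASA_RADII <- c(N = 1.55, CA = 2.00, C = 1.70, O = 1.52, SC = NA)

#' Solvent-accessible surface area (Shrake-Rupley sphere sampling)
#'
#' Sphere-point sampling with 960 points per site by default, probe radius
#' 1.4 Angstrom; site radii are N 1.55, CA 2.0, C 1.7, O 1.52 and the
#' per-residue sidechain nominal radius. Glycine's coincident centroid has
#' radius 0 and is skipped.
#'
#' @param x An `ma_conformation`, or a coordinate matrix (then `radii` is
#'   required).
#' @param probe Probe radius, Angstrom.
#' @param n_points Sphere sample points per site.
#' @param radii Per-site radii for the matrix method.
#' @param ... Unused.
#' @return Total SASA in Angstrom^2 (attribute `per_site` holds the split).
#' @export
sasa <- function(x, probe = 1.4, n_points = 960, ...) UseMethod("sasa")

#' @rdname sasa
#' @export
sasa.matrix <- function(x, probe = 1.4, n_points = 960, radii, ...) {
  per <- cpp_sasa(x, as.double(radii), probe, fibonacci_sphere(n_points))
  structure(sum(per), per_site = per)
}

#' @rdname sasa
#' @export
sasa.ma_conformation <- function(x, probe = 1.4, n_points = 960, ...) {
  n <- x$chain$n
  radii <- rep(unname(SASA_RADII[ATOM_NAMES]), n)
  radii[seq(5, 5 * n, 5)] <- x$chain$residues$sc_radius
  sasa(x$coords, probe = probe, n_points = n_points, radii = radii)
}

wrap_angle <- function(x) {
  x - 360 * floor(x / 360 + 0.5)
}

#' Circular RMSD between two torsion sets
#'
#' @param t1,t2 Numeric vectors of angles in degrees (equal length);
#'   `NA`s are dropped pairwise.
#' @return Root-mean-square circular difference, degrees.
#' @export
dihedral_rmsd <- function(t1, t2) {
  d <- wrap_angle(t1 - t2)
  sqrt(mean(d^2, na.rm = TRUE))
}

# all torsions of a conformation as one vector (phi then psi), phi[1] dropped
# (gauge)
torsion_vector <- function(conf) {
  c(conf$phi[-1], conf$psi)
}
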