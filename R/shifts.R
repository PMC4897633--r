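# Chemical-shift tables, the toy torsion->shift predictor standing in for a
# full empirical predictor, and the replica-averaged flat-bottom restraint.

SHIFT_ATOMS <- c("CA", "CB", "C")

#' Read / write a chemical-shift table
#'
#' TSV with header `residue atom shift sigma`; keys (residue, atom) must be
#' unique, sigma > 0.
#'
#' @param path File path.
#' @param table A shift tibble (columns `residue`, `atom`, `shift`, `sigma`).
#' @return `read_shift_table()` returns the validated tibble.
#' @export
read_shift_table <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("residue", "atom", "shift", "sigma")
  if (!all(need %in% names(raw))) {
    abort("Shift table must have columns: residue atom shift sigma.")
  }
  tab <- tibble::as_tibble(raw[need])
  tab$residue <- as.integer(tab$residue)
  if (!is.numeric(tab$shift) || anyNA(tab$shift)) abort("Non-numeric shifts.")
  validate_shift_table(tab)
}

#' @rdname read_shift_table
#' @export
write_shift_table <- function(table, path) {
  validate_shift_table(table)
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_shift_table <- function(table, chain = NULL) {
  if (anyDuplicated(table[c("residue", "atom")]) > 0) {
    abort("Duplicate (residue, atom) keys in shift table.")
  }
  if (any(table$sigma <= 0)) abort("sigma must be > 0.")
  if (!is.null(chain) && any(table$residue < 1 | table$residue > chain$n)) {
    abort("Shift table residues outside the chain.")
  }
  tibble::as_tibble(table)
}

#' Toy chemical-shift predictor
#'
#' A documented stand-in for an empirical shift predictor on the coarse
#' model: `delta(res, atom) = delta_coil(aa, atom) + w(phi, psi) *
#' delta_helix(atom)` with Gaussian helical-basin weight
#' `w = exp(-((phi + 57)^2 + (psi + 47)^2) / (2 s^2))`, s = 25 degrees.
#' Helix increments are (+2.6, -0.4, +1.9) ppm for (CA, CB, C). The
#' `"perturbed"` variant (different increments and width) supports
#' cross-validation against a predictor other than the restraining one.
#'
#' @param type `"default"` or `"perturbed"`.
#' @return An object of class `ma_predictor`: constants plus per-nucleus
#'   error estimates (ppm).
#' @export
shift_predictor <- function(type = c("default", "perturbed")) {
  type <- match.arg(type)
  if (type == "default") {
    structure(list(type = type, s = 25,
                   dhelix = c(CA = 2.6, CB = -0.4, C = 1.9),
                   coil_offset = c(CA = 0, CB = 0, C = 0),
                   errors = c(CA = 0.4, CB = 0.5, C = 0.4)),
              class = "ma_predictor")
  } else {
    structure(list(type = type, s = 28,
                   dhelix = c(CA = 2.2, CB = -0.6, C = 1.6),
                   coil_offset = c(CA = 0.10, CB = -0.10, C = 0.05),
                   errors = c(CA = 0.4, CB = 0.5, C = 0.4)),
              class = "ma_predictor")
  }
}

# Gaussian helical-basin weight of the predictor
helix_basin_weight <- function(phi, psi, s = 25) {
  d1 <- wrap_angle(phi + 57)
  d2 <- wrap_angle(psi + 47)
  exp(-(d1^2 + d2^2) / (2 * s^2))
}

coil_shift_lookup <- function(chain, residues, atoms) {
  coil <- random_coil_shifts()
  aa <- chain$residues$aa[residues]
  vapply(seq_along(residues), function(i) {
    coil[[atoms[i]]][match(aa[i], coil$aa)]
  }, numeric(1))
}

#' Predict chemical shifts for a conformation
#'
#' @param conf An `ma_conformation`.
#' @param residues Residue selection (default: assigned region 6-25).
#' @param atoms Nuclei, subset of CA, CB, C.
#' @param predictor An [shift_predictor()].
#' @return Tibble `residue`, `atom`, `shift` (ppm).
#' @export
predict_shifts <- function(conf, residues = NULL, atoms = SHIFT_ATOMS,
                           predictor = shift_predictor()) {
  bad <- setdiff(atoms, SHIFT_ATOMS)
  if (length(bad) > 0) abort(paste("Unknown atom name(s):", paste(bad, collapse = ", ")))
  residues <- default_range(conf$chain, residues)
  grid <- tidyr::expand_grid(residue = residues, atom = atoms)
  w <- helix_basin_weight(conf$phi[grid$residue], conf$psi[grid$residue],
                          predictor$s)
  coil <- coil_shift_lookup(conf$chain, grid$residue, grid$atom) +
    predictor$coil_offset[grid$atom]
  tibble::tibble(residue = grid$residue, atom = grid$atom,
                 shift = unname(coil + w * predictor$dhelix[grid$atom]))
}

# ensemble-mean predicted shifts (uniform weights)
ensemble_mean_shifts <- function(ens, residues = NULL, atoms = SHIFT_ATOMS,
                                 predictor = shift_predictor()) {
  residues <- default_range(ens$chain, residues)
  grid <- tidyr::expand_grid(residue = residues, atom = atoms)
  coil <- coil_shift_lookup(ens$chain, grid$residue, grid$atom) +
    predictor$coil_offset[grid$atom]
  # mean basin weight per residue over frames
  wbar <- vapply(residues, function(r) {
    mean(helix_basin_weight(ens$phi[, r], ens$psi[, r], predictor$s))
  }, numeric(1))
  names(wbar) <- as.character(residues)
  tibble::tibble(residue = grid$residue, atom = grid$atom,
                 shift = unname(coil + wbar[as.character(grid$residue)] *
                                  predictor$dhelix[grid$atom]))
}

#' Replica-averaged restraint specification
#'
#' Flat-bottom harmonic on the across-replica mean of the predicted shifts:
#' `E = k * sum_j max(0, |mean_delta_j - delta_exp_j| - eps_j)^2`. The
#' half-width eps defaults to the per-nucleus sigma of the shift table.
#'
#' @param k Force constant, kJ/mol/ppm^2.
#' @param epsilon Flat-bottom half-width (ppm); `NULL` uses table sigmas.
#' @param n_replicas Replica count M.
#' @param atoms Restrained nuclei.
#' @return An object of class `ma_restraint`.
#' @export
replica_restraint <- function(k = 10, epsilon = NULL, n_replicas = 4,
                              atoms = SHIFT_ATOMS) {
  stopifnot(k >= 0, n_replicas >= 1, is.null(epsilon) || all(epsilon >= 0))
  structure(list(k = k, epsilon = epsilon, n_replicas = n_replicas,
                 atoms = atoms),
            class = "ma_restraint")
}

#' Read / write a restraint configuration as YAML
#'
#' @param restraint An [replica_restraint()].
#' @param path File path.
#' @return `read_restraint_config()` returns an `ma_restraint`.
#' @export
write_restraint_config <- function(restraint, path) {
  yaml::write_yaml(list(k = restraint$k, epsilon = restraint$epsilon,
                        n_replicas = restraint$n_replicas,
                        atoms = as.list(restraint$atoms)), path)
  invisible(path)
}

#' @rdname write_restraint_config
#' @export
read_restraint_config <- function(path) {
  y <- yaml::read_yaml(path)
  replica_restraint(k = y$k, epsilon = unlist(y$epsilon),
                    n_replicas = y$n_replicas, atoms = unlist(y$atoms))
}

#' Replica-averaged restraint energy
#'
#' The defining property of replica averaging: only the across-replica mean
#' of the predicted shifts is restrained, so compensating deviations in
#' different replicas cost nothing.
#'
#' @param replica_confs List of exactly M `ma_conformation`s (one per
#'   replica).
#' @param table Shift table (tibble with `residue`, `atom`, `shift`,
#'   `sigma`).
#' @param restraint An [replica_restraint()].
#' @param predictor An [shift_predictor()].
#' @return Energy in kJ/mol; attribute `per_nucleus` holds the breakdown.
#' @export
replica_averaged_energy <- function(replica_confs, table,
                                    restraint = replica_restraint(),
                                    predictor = shift_predictor()) {
  if (length(replica_confs) != restraint$n_replicas) {
    abort(sprintf("Expected %d replica conformations, got %d.",
                  restraint$n_replicas, length(replica_confs)))
  }
  if (nrow(table) == 0) abort("Empty shift table.")
  table <- validate_shift_table(table, replica_confs[[1]]$chain)
  table <- dplyr::filter(table, .data$atom %in% restraint$atoms)
  preds <- lapply(replica_confs, function(cf) {
    predict_shifts(cf, residues = unique(table$residue),
                   atoms = unique(table$atom), predictor = predictor)
  })
  key <- paste(table$residue, table$atom)
  mean_pred <- Reduce(`+`, lapply(preds, function(p) {
    p$shift[match(key, paste(p$residue, p$atom))]
  })) / length(preds)
  eps <- if (is.null(restraint$epsilon)) table$sigma else
    rep_len(restraint$epsilon, nrow(table))
  viol <- pmax(0, abs(mean_pred - table$shift) - eps)
  per <- tibble::tibble(residue = table$residue, atom = table$atom,
                        mean_pred = mean_pred, target = table$shift,
                        eps = eps, energy = restraint$k * viol^2)
  structure(restraint$k * sum(viol^2), per_nucleus = per)
}

#' Back-calculation validation of a refined ensemble
#'
#' Compares the ensemble-mean predicted shifts to the experimental table,
#' per nucleus type. A nucleus type passes when the standard deviation of the
#' deviations lies within the predictor's error estimate. For
#' cross-validation, use a predictor other than the restraining one (the
#' `"perturbed"` variant is packaged for that purpose).
#'
#' @param ens An `ma_ensemble`.
#' @param table Shift table.
#' @param predictor An [shift_predictor()].
#' @return Tibble per atom type: `atom`, `n`, `mean_dev`, `sd_dev`,
#'   `error_estimate`, `pass`.
#' @export
backcalc_validate <- function(ens, table, predictor = shift_predictor()) {
  if (n_frames(ens) < 1) abort("Empty ensemble.")
  table <- validate_shift_table(table, ens$chain)
  resid <- intersect(unique(table$residue), seq_len(ens$chain$n))
  if (length(resid) == 0) abort("No overlap between table and chain residues.")
  pred <- ensemble_mean_shifts(ens, residues = resid,
                               atoms = unique(table$atom),
                               predictor = predictor)
  joined <- dplyr::inner_join(table, pred, by = c("residue", "atom"),
                              suffix = c("_exp", "_pred"))
  joined |>
    dplyr::mutate(dev = .data$shift_pred - .data$shift_exp) |>
    dplyr::group_by(.data$atom) |>
    dplyr::summarise(n = dplyr::n(), mean_dev = mean(.data$dev),
                     sd_dev = stats::sd(.data$dev), .groups = "drop") |>
    dplyr::mutate(error_estimate = predictor$errors[.data$atom],
                  pass = .data$sd_dev <= .data$error_estimate)
}
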