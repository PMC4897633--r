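# Ensemble container: ordered conformations with replica/cycle provenance and
# uniform weights. Torsions and coordinates are stored as dense arrays
# (frames are the third dimension of the coordinate array).

new_ensemble <- function(chain, phi, psi, coords = NULL, info = NULL) {
  phi <- rbind(phi); psi <- rbind(psi)
  f <- nrow(phi)
  if (is.null(coords)) {
    coords <- cpp_build_coords_many(phi, psi, chain$residues$sc_dist)
  }
  if (is.null(info)) {
    info <- tibble::tibble(frame = seq_len(f), replica = 1L, cycle = 1L,
                           temperature = NA_real_)
  }
  info$weight <- 1 / f
  structure(list(chain = chain, phi = phi, psi = psi, coords = coords,
                 info = info),
            class = "ma_ensemble")
}

#' Number of frames in an ensemble
#' @param ens An `ma_ensemble`.
#' @return Integer frame count.
#' @export
n_frames <- function(ens) nrow(ens$phi)

#' @export
print.ma_ensemble <- function(x, ...) {
  cat("<ma_ensemble> ", n_frames(x), " frames x ", x$chain$n, " residues (",
      length(unique(x$info$replica)), " replica(s))\n", sep = "")
  invisible(x)
}

#' Extract one frame as a conformation
#'
#' @param ens An `ma_ensemble`.
#' @param frame Frame index.
#' @return An `ma_conformation`.
#' @export
ensemble_conformation <- function(ens, frame) {
  stopifnot(frame >= 1, frame <= n_frames(ens))
  new_conformation(ens$chain, ens$coords[, , frame], ens$phi[frame, ],
                   ens$psi[frame, ])
}

#' Assemble an ensemble from conformations
#'
#' All conformations must share one chain; weights are uniform.
#'
#' @param confs List of `ma_conformation` objects.
#' @param info Optional frame metadata tibble.
#' @return An `ma_ensemble`.
#' @export
ensemble_from_conformations <- function(confs, info = NULL) {
  stopifnot(length(confs) >= 1)
  chain <- confs[[1]]$chain
  ns <- vapply(confs, function(cf) cf$chain$n, integer(1))
  if (!all(ns == chain$n)) abort("All frames must share one chain.")
  phi <- do.call(rbind, lapply(confs, `[[`, "phi"))
  psi <- do.call(rbind, lapply(confs, `[[`, "psi"))
  coords <- array(0, dim = c(5 * chain$n, 3, length(confs)))
  for (f in seq_along(confs)) coords[, , f] <- confs[[f]]$coords
  new_ensemble(chain, phi, psi, coords, info)
}

#' @export
as_tibble.ma_ensemble <- function(x, ...) x$info

# ----------------------------------------------------------------- PDB I/O --

#' Write an ensemble as a multi-model PDB file
#'
#' Coarse atoms are named N, CA, C, O, SC with 1-based residue numbering;
#' models are delimited by MODEL/ENDMDL. The gauge torsion `phi[1]` of each
#' model is stored in a `REMARK 100 PHI1` header line so torsions round-trip.
#'
#' @param ens An `ma_ensemble`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ens, path) {
  chain <- ens$chain
  n <- chain$n
  res3 <- chain$residues$name3
  lines <- character(0)
  lines <- c(lines, sprintf("REMARK 100 PHI1 %s",
                            paste(sprintf("%.4f", ens$phi[, 1]), collapse = " ")))
  for (f in seq_len(n_frames(ens))) {
    lines <- c(lines, sprintf("MODEL     %4d", f))
    X <- ens$coords[, , f]
    k <- 0L
    rec <- character(5 * n)
    for (i in seq_len(n)) {
      for (s in seq_len(5)) {
        k <- k + 1L
        rec[k] <- sprintf("ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                          k, ATOM_NAMES[s], res3[i], i,
                          X[k, 1], X[k, 2], X[k, 3])
      }
    }
    lines <- c(lines, rec, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a multi-model PDB file into an ensemble
#'
#' Expects the coarse five-site dialect written by [write_ensemble_pdb()].
#' External PDBs with the same atom names can be read against a matching
#' chain. Torsions are extracted from coordinates; `phi[1]` is taken from the
#' `REMARK 100 PHI1` header when present.
#'
#' @param path PDB file.
#' @param chain Optional [peptide_chain()]; inferred from residue names
#'   otherwise.
#' @return An `ma_ensemble`.
#' @export
read_ensemble_pdb <- function(path, chain = NULL) {
  txt <- readLines(path)
  phi1 <- NULL
  rem <- grep("^REMARK 100 PHI1", txt, value = TRUE)
  if (length(rem) == 1) {
    phi1 <- as.numeric(strsplit(sub("^REMARK 100 PHI1 +", "", rem), " +")[[1]])
  }
  atom <- txt[startsWith(txt, "ATOM  ") | startsWith(txt, "HETATM")]
  if (length(atom) == 0) abort("No ATOM records found.")
  name <- trimws(substr(atom, 13, 16))
  res3 <- trimws(substr(atom, 18, 20))
  resno <- as.integer(substr(atom, 23, 26))
  x <- as.numeric(substr(atom, 31, 38))
  y <- as.numeric(substr(atom, 39, 46))
  z <- as.numeric(substr(atom, 47, 54))
  ends <- grep("^ENDMDL", txt)
  n_models <- if (length(ends) > 0) length(ends) else 1L
  per <- length(atom) / n_models
  if (per != round(per)) abort("Models differ in atom count.")
  per <- as.integer(per)
  if (is.null(chain)) {
    first <- seq_len(per)
    ca <- first[name[first] == "CA"]
    aa1 <- names(AA3)[match(res3[ca], AA3)]
    if (any(is.na(aa1))) abort("Unknown residue names in PDB.")
    chain <- peptide_chain(paste(aa1, collapse = ""))
  }
  if (per != 5 * chain$n) abort("Atom count does not match 5 sites/residue.")
  confs <- vector("list", n_models)
  for (f in seq_len(n_models)) {
    idx <- ((f - 1) * per + 1):(f * per)
    X <- cbind(x[idx], y[idx], z[idx])
    ord <- order(resno[idx], match(name[idx], ATOM_NAMES))
    confs[[f]] <- conformation_from_coords(chain, X[ord, , drop = FALSE],
                                           phi1 = if (!is.null(phi1)) phi1[f] else -57)
  }
  ensemble_from_conformations(confs)
}
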