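#' Build a coarse peptide chain
#'
#' Creates the per-residue parameter object used throughout the package:
#' sequence, charge and hydrophobicity classes, sidechain-centroid geometry.
#' The N-terminal amine is counted as a positive charge carried on the
#' backbone N atom of residue 1, so residue 1 is classed positive unless its
#' sidechain is negative.
#'
#' @param sequence One-letter amino-acid string (length >= 2), 1-based
#'   residue indexing.
#' @param params Residue property table, see [residue_properties()].
#' @return An object of class `ma_chain`.
#' @export
peptide_chain <- function(sequence, params = residue_properties()) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (length(aa) < 2) {
    abort("`sequence` must contain at least 2 residues.")
  }
  bad <- setdiff(aa, params$aa)
  if (length(bad) > 0) {
    abort(paste0("Unknown residue letter(s): ", paste(unique(bad), collapse = ", ")))
  }
  res <- tibble::tibble(residue = seq_along(aa), aa = aa) |>
    dplyr::left_join(params, by = "aa")
  # N-terminal amine counted positive
  if (res$charge_class[1] == "neutral") res$charge_class[1] <- "positive"
  structure(
    list(sequence = paste(aa, collapse = ""), n = length(aa),
         residues = res, nterm_charge = 1),
    class = "ma_chain"
  )
}

#' alpha-synuclein anchor chain fixture
#'
#' [peptide_chain()] applied to [alpha_syn_anchor_sequence()].
#' @return An `ma_chain` of length 30.
#' @export
alpha_syn_chain <- function() {
  peptide_chain(alpha_syn_anchor_sequence())
}

#' @export
print.ma_chain <- function(x, ...) {
  cat("<ma_chain> ", x$n, " residues: ", x$sequence, "\n", sep = "")
  invisible(x)
}

#' Write or read residue parameters as YAML
#'
#' Charge and hydrophobicity tables are serialisable so a user can supply a
#' modified parameterisation.
#'
#' @param params Residue property table (as from [residue_properties()]).
#' @param path File path.
#' @return `read_residue_params()` returns the parameter tibble.
#' @export
write_residue_params <- function(params, path) {
  yaml::write_yaml(lapply(split(params, params$aa), function(r) {
    list(name3 = r$name3, sc_dist = r$sc_dist, sc_radius = r$sc_radius,
         sc_charge = r$sc_charge, charge_class = r$charge_class,
         hydro_class = r$hydro_class)
  }), path)
  invisible(path)
}

#' @rdname write_residue_params
#' @export
read_residue_params <- function(path) {
  y <- yaml::read_yaml(path)
  dplyr::bind_rows(lapply(names(y), function(a) {
    tibble::tibble(aa = a, name3 = y[[a]]$name3, sc_dist = y[[a]]$sc_dist,
                   sc_radius = y[[a]]$sc_radius, sc_charge = y[[a]]$sc_charge,
                   charge_class = y[[a]]$charge_class,
                   hydro_class = y[[a]]$hydro_class)
  })) |>
    dplyr::arrange(.data$aa)
}

# internal: resolve a residue range against a chain, with the assigned-region
# default (6-25 where the chain is long enough, otherwise the whole chain)
default_range <- function(chain, residues = NULL) {
  if (is.null(residues)) {
    residues <- if (chain$n >= 25) 6:25 else seq_len(chain$n)
  }
  residues <- sort(unique(as.integer(residues)))
  if (any(residues < 1 | residues > chain$n)) {
    abort("`residues` outside the chain.")
  }
  residues
}
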