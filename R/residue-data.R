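# Residue-level parameter tables for the coarse model. Sidechain centroid
# distances are centroid-from-CA values for an extended rotamer; radii are
# nominal excluded-volume radii. Random-coil shifts are generic backbone
# carbon values in ppm; the helix deltas are the secondary-shift increments
# applied at full helical weight. Glycine is assigned a nominal pseudo-CB
# coil value so that a complete (residue x {CA,CB,C}) table can be built for
# any sequence; in the coarse model the sidechain centroid of glycine
# coincides with CA.

AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
         H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
         P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
         W = "TRP", Y = "TYR")

#' Residue property table of the coarse model
#'
#' One row per amino acid: charge class (Lys/Arg positive, Asp/Glu negative,
#' His neutral), hydrophobicity class (hydrophobic for A, V, L, I, M, F),
#' sidechain-centroid distance from CA (Angstrom) and nominal centroid radius
#' (Angstrom). These defaults parameterise [peptide_chain()].
#'
#' @return A tibble with columns `aa`, `name3`, `charge_class`,
#'   `hydro_class`, `sc_charge`, `sc_dist`, `sc_radius`.
#' @export
residue_properties <- function() {
  tibble::tibble(
    aa = AA1,
    name3 = unname(AA3[AA1]),
    sc_dist = c(1.53, 2.07, 2.47, 3.11, 3.41, 0.00, 3.16, 2.31, 3.52, 2.60,
                2.95, 2.49, 1.87, 3.09, 4.12, 1.90, 1.93, 1.97, 3.86, 3.84),
    sc_radius = c(1.8, 2.2, 2.4, 2.6, 2.8, 0.0, 2.7, 2.6, 2.6, 2.6,
                  2.6, 2.4, 2.3, 2.6, 2.8, 2.0, 2.2, 2.4, 3.0, 2.9),
    sc_charge = dplyr::case_when(
      aa %in% c("K", "R") ~ 1,
      aa %in% c("D", "E") ~ -1,
      TRUE ~ 0
    ),
    charge_class = dplyr::case_when(
      sc_charge > 0 ~ "positive",
      sc_charge < 0 ~ "negative",
      TRUE ~ "neutral"
    ),
    hydro_class = ifelse(aa %in% c("A", "V", "L", "I", "M", "F"),
                         "hydrophobic", "other")
  )
}

#' Random-coil chemical shifts of the toy predictor
#'
#' @return A tibble with columns `aa`, `CA`, `CB`, `C` (ppm).
#' @export
random_coil_shifts <- function() {
  tibble::tibble(
    aa = AA1,
    CA = c(52.5, 58.2, 54.2, 56.6, 57.7, 45.1, 55.0, 61.1, 56.2, 55.1,
           55.4, 53.1, 63.3, 55.7, 56.0, 58.3, 61.8, 62.2, 57.5, 57.9),
    CB = c(19.1, 28.0, 41.1, 29.9, 39.6, 46.0, 29.0, 38.8, 32.9, 42.4,
           32.9, 38.9, 32.1, 29.4, 30.9, 63.8, 69.8, 32.9, 29.6, 38.8),
    C = c(177.8, 174.6, 176.3, 176.6, 175.8, 174.9, 174.1, 176.4, 176.6,
          177.6, 176.3, 175.2, 177.3, 176.0, 176.3, 174.6, 174.7, 176.3,
          176.1, 175.9)
  )
}

#' alpha-synuclein membrane-anchor sequence (residues 1-30)
#'
#' @return One-letter sequence string of length 30.
#' @export
alpha_syn_anchor_sequence <- function() {
  "MDVFMKGLSKAKEGVVAAAEKTKQGVAEAA"
}
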