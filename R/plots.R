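# ggplot2 figures for the analysis products.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a free-energy surface
#'
#' @param object An `ma_fes`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ma_fes <- function(object, ...) {
  ggplot(dplyr::filter(object$grid, !is.na(.data$free_energy)),
         aes(x = .data$rmsd, y = .data$dipole, fill = .data$free_energy)) +
    geom_raster() +
    scale_fill_viridis_c(direction = -1, name = "F (kJ/mol)") +
    geom_point(data = object$basins, aes(x = .data$rmsd, y = .data$dipole),
               inherit.aes = FALSE, shape = 4, colour = "red") +
    labs(x = expression("C" * alpha * " RMSD to ideal helix (Å)"),
         y = "dipole moment (e nm)") +
    theme_minimal()
}

#' Plot a contact-occupancy map
#'
#' @param object An `ma_contact_map` (from [salt_bridge_occupancy()] or
#'   [hydrophobic_contact_map()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ma_contact_map <- function(object, ...) {
  both <- dplyr::bind_rows(
    object,
    dplyr::rename(object, res_i = "res_j", res_j = "res_i")
  )
  ggplot(both, aes(x = .data$res_i, y = .data$res_j,
                   fill = .data$occupancy)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1), name = "occupancy") +
    labs(x = "residue", y = "residue",
         title = paste(unique(object$type), "contacts")) +
    coord_equal() +
    theme_minimal()
}

#' Plot a PRE attenuation profile
#'
#' @param object An `ma_pre_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ma_pre_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$residue, y = .data$attenuation,
                     fill = .data$broadened)) +
    geom_col() +
    scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                      name = "broadened") +
    labs(x = "residue", y = "attenuation A",
         title = paste("PRE profile, label", attr(object, "label"))) +
    ylim(0, 1) +
    theme_minimal()
}

#' Per-residue helix population plot
#'
#' @param pop Tibble from [helix_population()].
#' @return A ggplot.
#' @export
plot_helix_population <- function(pop) {
  ggplot(pop, aes(x = .data$residue, y = .data$helix_fraction)) +
    geom_col(fill = "steelblue") +
    ylim(0, 1) +
    labs(x = "residue", y = "helix population") +
    theme_minimal()
}

#' Per-residue insertion-depth plot
#'
#' @param depths Tibble from [residue_depths()].
#' @return A ggplot.
#' @export
plot_depth_profile <- function(depths) {
  ggplot(depths, aes(x = .data$residue, y = .data$mean_depth)) +
    geom_ribbon(aes(ymin = .data$mean_depth - .data$sd_depth,
                    ymax = .data$mean_depth + .data$sd_depth),
                fill = "grey80") +
    geom_line() +
    geom_point() +
    labs(x = "residue", y = "depth above midplane (Å)") +
    theme_minimal()
}

#' Convergence-metric block plot
#'
#' @param metrics Tibble from [convergence_metrics()].
#' @return A ggplot.
#' @export
plot_convergence <- function(metrics) {
  long <- tidyr::pivot_longer(metrics, -"block", names_to = "metric")
  ggplot(long, aes(x = .data$block, y = .data$value)) +
    geom_line() +
    geom_point() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "block", y = NULL) +
    theme_minimal()
}
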