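# broom-style tidiers for sampled and projected objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sampling result
#'
#' Per-cycle, per-replica traces: acceptance rate, physical and restraint
#' energies, move width.
#'
#' @param x An `ma_sampling`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ma_sampling <- function(x, ...) {
  x$traces
}

#' One-row summary of a sampling result
#'
#' @param x An `ma_sampling`.
#' @param ... Unused.
#' @return A one-row tibble: frames collected, cycles, replicas, mean
#'   acceptance over collected cycles, final energies.
#' @export
glance.ma_sampling <- function(x, ...) {
  disc <- x$accounting$discarded_cycles
  kept <- dplyr::filter(x$traces, .data$cycle > disc)
  tibble::tibble(
    n_frames = n_frames(x$ensemble),
    n_cycles = x$schedule$n_cycles,
    n_replicas = x$config$n_replicas,
    discarded_cycles = disc,
    mean_acceptance = mean(kept$acceptance),
    final_e_physical = mean(x$traces$e_physical[
      x$traces$cycle == max(x$traces$cycle)]),
    final_e_restraint = x$traces$e_restraint[nrow(x$traces)]
  )
}

#' Tidy a free-energy surface
#'
#' @param x An `ma_fes`.
#' @param ... Unused.
#' @return Long tibble of grid cells (`rmsd`, `dipole`, `count`,
#'   `free_energy`).
#' @export
tidy.ma_fes <- function(x, ...) {
  x$grid
}

#' One-row summary of a free-energy surface
#'
#' @param x An `ma_fes`.
#' @param ... Unused.
#' @return A one-row tibble: frame count, occupied bins, basin count and the
#'   main basin's coordinates and population.
#' @export
glance.ma_fes <- function(x, ...) {
  main <- x$basins[which.max(x$basins$population), ]
  tibble::tibble(
    n_frames = nrow(x$coords),
    n_bins_occupied = sum(x$grid$count > 0),
    n_basins = nrow(x$basins),
    main_basin_rmsd = main$rmsd,
    main_basin_dipole = main$dipole,
    main_basin_population = main$population,
    temperature = x$temperature
  )
}
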