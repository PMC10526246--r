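#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

species_colors <- c(H1 = "#2e7d32", T1 = "#f9a825", H2 = "#1565c0",
                    T2 = "#c62828", W = "#90a4ae")

#' @export
autoplot.dpd_density_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pos, y = .data$density,
                                       colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = species_colors) +
    ggplot2::labs(x = sprintf("%s (rc)", attr(object, "axis")),
                  y = expression(density ~ (r[c]^-3)), colour = "species") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dpd_density_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$u, y = .data$v,
                                       fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = sprintf("%s (rc)", substr(attr(object, "plane"), 1, 1)),
                  y = sprintf("%s (rc)", substr(attr(object, "plane"), 2, 2)),
                  fill = "beads") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dpd_velocity_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$mean_vx)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "z (rc)", y = expression(bar(v)[x] ~ (r[c] / tau))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dpd_shape_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$mean_delta,
                                       colour = factor(.data$type))) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(`1` = "#2e7d32", `2` = "#1565c0"),
                                 labels = c("type I", "type II")) +
    ggplot2::labs(x = expression(time ~ (tau)),
                  y = expression(group("<", delta, ">")), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the energy relaxation of a run
#'
#' Total and potential energy against time, optionally overlaid with the
#' stage boundaries from [segment_stages()].
#'
#' @param run A `dpd_run` (or its energy tibble).
#' @param stages Optional `dpd_stages` tibble.
#' @return A ggplot.
#' @export
plot_energy <- function(run, stages = NULL) {
  energy <- if (inherits(run, "dpd_run")) run$energy else run
  long <- tidyr::pivot_longer(energy[, c("time", "total", "pe_pair")],
                              -"time", names_to = "series")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                          colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(time ~ (tau)), y = "energy (kBT)") +
    ggplot2::theme_minimal()
  if (!is.null(stages) && nrow(stages) > 1) {
    p <- p + ggplot2::geom_vline(xintercept = stages$t_start[-1],
                                 linetype = "dashed", alpha = 0.5)
  }
  p
}

#' Plot a phase-diagram sweep
#'
#' Tail-length grid tiled by phase label, faceted by shear condition (and
#' concentration when several are present).
#'
#' @param sweep Result tibble of [run_sweep()].
#' @return A ggplot.
#' @export
plot_phase_diagram <- function(sweep) {
  p <- ggplot2::ggplot(sweep, ggplot2::aes(x = .data$nt1, y = .data$nt2,
                                           fill = .data$label)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(N[T1]), y = expression(N[T2]), fill = "phase") +
    ggplot2::theme_minimal()
  if (length(unique(sweep$phi)) > 1) {
    p + ggplot2::facet_grid(phi ~ shear)
  } else {
    p + ggplot2::facet_wrap(~shear)
  }
}
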