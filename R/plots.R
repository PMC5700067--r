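#' @importFrom ggplot2 aes autoplot ggplot geom_line geom_point geom_raster
#'   geom_path labs facet_wrap scale_fill_gradient theme_minimal annotate
#' @export
ggplot2::autoplot

#' Plot a simulation time series
#'
#' Tumor radius over time with the per-kind cell counts in a second facet.
#'
#' @param object An `eln_sim` from [run_simulation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eln_sim <- function(object, ...) {
  long <- tidy.eln_sim(object)
  ggplot(long, aes(x = .data$day, y = .data$count,
                   colour = .data$kind)) +
    geom_line() +
    geom_line(aes(y = .data$radius_um / max(.data$radius_um) *
                    max(.data$count), colour = NULL),
              data = dplyr::distinct(long, .data$day, .data$radius_um),
              linetype = 2) +
    labs(x = "time (days)", y = "cells (dashed: scaled tumor radius)",
         colour = "cell kind") +
    theme_minimal()
}

#' Plot the averaged trajectories of an RFC sweep
#'
#' The replicate-averaged tumor radius over time, one line per RFC arm, plus
#' the end-of-run radius per arm; the two panels correspond to the standard
#' presentation of this experiment.
#'
#' @param object An [rfc_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rfc_sweep <- function(object, ...) {
  tr <- object$trajectories %>%
    mutate(day = .data$time_min / 1440,
           arm = factor(.data$rfc_count))
  ggplot(tr, aes(x = .data$day, y = .data$mean_radius_um,
                 colour = .data$arm)) +
    geom_line() +
    labs(x = "time (days)", y = "mean tumor radius (um)",
         colour = "RFC count",
         title = paste0("Tumor dynamics, average of ", object$replicates,
                        " runs per arm")) +
    theme_minimal()
}

#' Plot day-30 tumor size per sweep arm
#'
#' @param sweep An [rfc_sweep()] result.
#' @return A ggplot object.
#' @export
plot_sweep_endpoints <- function(sweep) {
  stopifnot(inherits(sweep, "rfc_sweep"))
  ggplot(sweep$summary,
         aes(x = factor(.data$rfc_count), y = .data$day30_radius_um)) +
    geom_point(size = 3) +
    labs(x = "RFC count", y = "tumor radius at horizon (um)") +
    theme_minimal()
}

#' Plot a chemokine field raster
#'
#' @param field A [gradient_field()].
#' @param xlim,ylim Plot ranges (um); default covers sources plus a margin.
#' @param n Raster resolution.
#' @return A ggplot object.
#' @export
plot_field <- function(field, xlim = NULL, ylim = NULL, n = 151) {
  stopifnot(inherits(field, "gradient_field"))
  s <- field$sources
  if (is.null(xlim)) {
    xlim <- if (nrow(s) > 0) range(s$x) + c(-3, 3) * max(s$sigma)
            else c(-1000, 1000)
  }
  if (is.null(ylim)) {
    ylim <- if (nrow(s) > 0) range(s$y) + c(-3, 3) * max(s$sigma)
            else c(-1000, 1000)
  }
  ras <- field_raster(field, xlim, ylim, n = n, normalize = TRUE)
  ggplot(ras, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient(low = "white", high = "grey20") +
    labs(x = "x (um)", y = "y (um)", fill = "relative\nconcentration") +
    theme_minimal()
}

#' Snapshot plot of the agents around the tumor
#'
#' Renders a cell-position snapshot: the tumor disc, the motile cells by
#' kind, and the RFC patch.
#'
#' @param cells Agent tibble (as from [init_simulation()] or the
#'   `final_agents` attribute of a run).
#' @param tumor_radius Tumor radius (um).
#' @return A ggplot object.
#' @export
plot_agents <- function(cells, tumor_radius) {
  stopifnot(is.data.frame(cells))
  th <- seq(0, 2 * pi, length.out = 181)
  disc <- tibble(x = tumor_radius * cos(th), y = tumor_radius * sin(th))
  ggplot(cells, aes(x = .data$x, y = .data$y)) +
    geom_path(data = disc, colour = "goldenrod") +
    geom_point(aes(colour = .data$kind, shape = .data$kind), size = 1) +
    labs(x = "x (um)", y = "y (um)") +
    theme_minimal()
}
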