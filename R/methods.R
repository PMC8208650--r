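#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation into its spike raster
#'
#' @param x An `mec_sim`.
#' @param ... Unused.
#' @return The spikes tibble (`trial`, `neuron`, `cell_type`, `time`).
#' @export
tidy.mec_sim <- function(x, ...) x$spikes

#' One-row summary of a simulation
#'
#' @param x An `mec_sim`.
#' @param ... Unused.
#' @return Tibble with cell counts, trial count, spike count, duration,
#'   integration step and clamp count.
#' @export
glance.mec_sim <- function(x, ...) {
  tibble::tibble(
    n_stellate = x$network$n_stellate,
    n_interneuron = x$network$n_interneuron,
    n_trials = length(unique(x$spikes$trial)),
    n_spikes = nrow(x$spikes),
    duration = x$config$duration,
    dt = x$config$dt,
    clamp_count = x$clamp_count)
}

#' @export
tidy.mec_experiment <- function(x, ...) x$predicates

#' @export
glance.mec_experiment <- function(x, ...) {
  tibble::tibble(name = x$name, seed = x$seed,
                 n_predicates = nrow(x$predicates),
                 n_pass = sum(x$predicates$pass))
}

#' @export
tidy.reliability_summary <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.reliability_summary <- function(x, ...) {
  tibble::tibble(n_neurons = nrow(x),
                 median_distance = stats::median(x$mean_distance),
                 mean_distance = mean(x$mean_distance))
}

#' Raster plot of a simulation
#'
#' Spike raster with trials stacked within each neuron row, stellate cells
#' and interneurons coloured separately.
#'
#' @param object An `mec_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mec_sim <- function(object, ...) {
  sp <- object$spikes
  n_tr <- max(sp$trial, 1)
  sp$y <- sp$neuron + (sp$trial - 1) / n_tr * 0.8
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$time, y = .data$y,
                                   colour = .data$cell_type)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::scale_colour_manual(values = c(stellate = "black",
                                            interneuron = "firebrick")) +
    ggplot2::labs(x = "time (ms)", y = "neuron", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Polar plot of a phase histogram
#'
#' @param object A [phase_histogram()] result.
#' @param ... Unused.
#' @return A ggplot in polar coordinates.
#' @export
autoplot.phase_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_center, y = .data$count)) +
    ggplot2::geom_col(width = 2 * pi / nrow(object), fill = "grey30") +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 2 * pi),
                                breaks = c(0, pi / 2, pi, 3 * pi / 2),
                                labels = c("0", "π/2", "π",
                                           "3π/2")) +
    ggplot2::labs(x = "theta phase", y = "spikes") +
    ggplot2::theme_minimal()
}

#' Reliability summary plot
#'
#' @param object A [reliability()] result.
#' @param ... Unused.
#' @return A ggplot of per-neuron mean pairwise SPIKE distance.
#' @export
autoplot.reliability_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$neuron),
                                       y = .data$mean_distance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "neuron", y = "mean pairwise SPIKE distance") +
    ggplot2::theme_minimal()
}

#' Voltage-trace plot
#'
#' @param sim An `mec_sim` with recorded traces.
#' @param neurons Neuron ids to show (default: all recorded).
#' @return A ggplot of stacked voltage traces.
#' @export
plot_traces <- function(sim, neurons = NULL) {
  tr <- sim$traces
  if (!is.null(neurons)) tr <- tr[tr$neuron %in% neurons, ]
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time, y = .data$v,
                                   group = interaction(.data$neuron,
                                                       .data$trial))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$neuron)) +
    ggplot2::labs(x = "time (ms)", y = "V (mV)") +
    ggplot2::theme_minimal()
}
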