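# paper-style state colors: clonogenic white, I red, M blue, W green
.state_colors <- c(CLONOGENIC = "white", I = "#d62728", M = "#1f77b4",
                   W = "#2ca02c", DEAD = "grey70")

#' Plot cell counts of a lineage run
#'
#' State-resolved counts (M, I, W, total) over time on a log-friendly linear
#' axis.
#'
#' @param object A `lineage_sim` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lineage_sim <- function(object, ...) {
  df <- state_counts(object)
  long <- tidyr::pivot_longer(df, c("total", "M", "I", "W"),
                              names_to = "series", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$n,
                                     color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time step (cell cycles)", y = "cells",
                  color = NULL,
                  title = sprintf("Lineage model, c = %d", object$params$c)) +
    ggplot2::theme_minimal()
}

#' Plot a rosette snapshot
#'
#' Planar cell map at time `t`, colored by state with the conventional map
#' (clonogenic white, immature red, mature blue, wholly mature green).
#'
#' @param object A `rosette_sim` object.
#' @param t Snapshot time (default: final step).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rosette_sim <- function(object, t = object$params$T, ...) {
  cc <- cells_at(object, t)
  ggplot2::ggplot(cc, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$state)) +
    ggplot2::geom_point(shape = 21, size = 3, color = "grey30") +
    ggplot2::scale_fill_manual(values = .state_colors, drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Rosette at t = %d (c = %d, R = %g°)",
                                  t, object$params$c, object$params$R),
                  x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a continuous-model trajectory
#'
#' Compartment sizes (M, I, W1, W2) over time.
#'
#' @param object An `ode_trajectory` tibble from [integrate_compartments()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ode_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("M", "I", "W1", "W2"),
                              names_to = "compartment", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$n,
                                     color = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (units of 1/k1)", y = "compartment size",
                  color = NULL) +
    ggplot2::theme_minimal()
}
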