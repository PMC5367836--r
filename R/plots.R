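#' Plot a simulated trajectory
#'
#' Compartment abundances (percent of initial total) against time, with
#' pulse windows shaded.
#'
#' @param traj Trajectory from [simulate_protocol()].
#' @param protocol Optional protocol tibble; when supplied, label-on windows
#'   are shaded.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj, protocol = NULL) {
  long <- tidyr::pivot_longer(as_tibble(traj), -"time_h",
                              names_to = "compartment", values_to = "percent")
  long$compartment <- factor(long$compartment, levels = .compartments,
                             labels = c("G0/G1", "S", "G2/M",
                                        "G0/G1 labelled", "S labelled",
                                        "G2/M labelled"))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time_h, .data$percent,
                                          colour = .data$compartment))
  if (!is.null(protocol)) {
    pulses <- protocol[protocol$label_on, ]
    p <- p + ggplot2::geom_rect(
      data = pulses,
      ggplot2::aes(xmin = .data$start_h, xmax = .data$end_h),
      ymin = -Inf, ymax = Inf, fill = "grey85", colour = NA,
      inherit.aes = FALSE
    )
  }
  p + ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "time (h)", y = "% of cells", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot edu_trajectory
#' @export
autoplot.edu_trajectory <- function(object, ...) plot_trajectory(object, ...)

#' Dot-plot view of a synthetic event table
#'
#' EdU intensity (log10 units) against DNA content, coloured by gated class,
#' with the gate boundaries drawn -- the synthetic counterpart of the
#' cytometry dot plot the triplets are read from.
#'
#' @param events Event tibble from [generate_events()].
#' @param gates Gate boundaries, see [default_gates()].
#' @param max_events Thin to at most this many points (default 20000).
#' @return A ggplot object.
#' @export
plot_dot_plot <- function(events, gates = default_gates(), max_events = 20000) {
  if (nrow(events) > max_events) {
    events <- events[seq(1, nrow(events), length.out = max_events), ]
  }
  ggplot2::ggplot(events, ggplot2::aes(.data$dna_content, .data$edu_intensity,
                                       colour = .data$true_class)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::geom_hline(yintercept = gates$edu_threshold, linetype = 2) +
    ggplot2::geom_vline(
      xintercept = c(gates$dna_apoptotic_max, gates$dna_g1_lo, gates$dna_g1_hi,
                     gates$dna_g2m_lo, gates$dna_g2m_hi, gates$dna_engulfed_min),
      linetype = 3, colour = "grey40"
    ) +
    ggplot2::scale_x_continuous(trans = "log10") +
    ggplot2::labs(x = "DNA content (linear a.u., log axis)",
                  y = "EdU intensity (log10 a.u.)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the rate-versus-labelled-percentage regression
#'
#' @param x An `edu_regression` from [rate_vs_edu_regression()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_rate_regression <- function(x, ...) {
  stopifnot(inherits(x, "edu_regression"))
  ggplot2::ggplot(x$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = x$slope, intercept = x$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "% EdU+ cells at sacrifice",
                  y = "fitted proliferation rate (fraction/day)") +
    ggplot2::theme_minimal()
}

#' @method autoplot edu_regression
#' @export
autoplot.edu_regression <- function(object, ...) plot_rate_regression(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
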