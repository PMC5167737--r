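# ggplot2 views of the result types.

synchrony_palette <- c(red = "#d73027", green = "#1a9850", blue = "#4575b4",
                       black = "#252525")

#' Plot a sweep grid as an amplitude-frequency entrainment map
#'
#' Tiles coloured by synchrony category (red = most synchronous, black =
#' least); cells whose synchrony patterns match the configured experimental
#' reference are marked with a dot.
#'
#' @param object A `sweep_grid`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sweep_grid <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$omega0, .data$A)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$category), colour = "white") +
    ggplot2::scale_fill_manual(values = synchrony_palette, na.value = "grey80",
                               name = "synchrony") +
    ggplot2::labs(x = "input frequency omega0 (Hz)",
                  y = "input amplitude A",
                  title = sprintf("g_syn = %g, I_app = %g (%s input)",
                                  attr(object, "g_syn"), attr(object, "i_app"),
                                  attr(object, "mode")))
  if (any(df$matched %in% TRUE)) {
    p <- p + ggplot2::geom_point(data = df[which(df$matched), ], size = 0.8)
  }
  p
}

#' Plot minimal-amplitude curves
#'
#' @param object A `minimal_amplitude_curve` (or several row-bound ones).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.minimal_amplitude_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$omega0, .data$min_amplitude,
                                   linetype = factor(.data$target))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "input frequency omega0 (Hz)",
                  y = "minimal amplitude", linetype = "target components")
}

#' Raster and trace overview of a simulation
#'
#' STN spike raster over the analysis window.
#'
#' @param object A `stn_gpe_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stn_gpe_sim <- function(object, ...) {
  df <- purrr::imap_dfr(object$spikes, function(s, i) {
    tibble::tibble(neuron = i, time = s$times[s$times >= object$transient])
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time / 1000, .data$neuron)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::scale_y_continuous(breaks = seq_len(ncol(object$v_stn))) +
    ggplot2::labs(x = "time (s)", y = "STN neuron")
}

#' First-return map scatter plot
#'
#' Consecutive once-per-cycle phase differences `(phi[i], phi[i + 1])`,
#' coloured by map region.
#'
#' @param map A `return_map_series`.
#' @return A ggplot.
#' @export
plot_return_map <- function(map) {
  part <- partition_regions(map)
  phi <- map$phi
  df <- tibble::tibble(phi_i = phi[-length(phi)], phi_next = phi[-1],
                       region = factor(part$labels))
  ggplot2::ggplot(df, ggplot2::aes(.data$phi_i, .data$phi_next,
                                   colour = .data$region)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = wrap_phase(part$center + c(-1, 1) * pi / 2),
                        linetype = "dotted") +
    ggplot2::coord_equal(xlim = c(-pi, pi), ylim = c(-pi, pi)) +
    ggplot2::labs(x = expression(phi[i]), y = expression(phi[i + 1]))
}
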