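# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation into per-neuron summaries
#'
#' @param x A `stn_gpe_sim`.
#' @param ... Unused.
#' @return A tibble with one row per STN neuron: spike count and mean firing
#'   rate over the analysis window.
#' @export
tidy.stn_gpe_sim <- function(x, ...) {
  win_s <- (x$duration - x$transient) / 1000
  purrr::imap_dfr(x$spikes, function(s, i) {
    k <- sum(s$times >= x$transient)
    tibble::tibble(neuron = i, population = "STN", n_spikes = k,
                   rate_hz = k / win_s)
  })
}

#' @rdname tidy.stn_gpe_sim
#' @return `glance()`: a one-row tibble with run-level settings and the mean
#'   STN rate.
#' @export
glance.stn_gpe_sim <- function(x, ...) {
  td <- tidy.stn_gpe_sim(x)
  tibble::tibble(
    duration_ms = x$duration, transient_ms = x$transient, dt_ms = x$dt,
    seed = x$seed, input_mode = x$input_spec$mode,
    g_syn = x$config$synapse$gpe_to_stn$g_syn, i_app = x$config$gpe$I_app,
    mean_stn_rate_hz = mean(td$rate_hz)
  )
}

#' Tidy a synchrony score
#'
#' @param x A `synchrony_score`.
#' @param ... Unused.
#' @return A tibble with one row per principal component: variance fraction
#'   and cumulative fraction.
#' @export
tidy.synchrony_score <- function(x, ...) {
  tibble::tibble(component = seq_along(x$variance_fractions),
                 variance_fraction = x$variance_fractions,
                 cumulative = cumsum(x$variance_fractions))
}

#' @rdname tidy.synchrony_score
#' @export
glance.synchrony_score <- function(x, ...) {
  tibble::tibble(component_count = x$component_count, category = x$category,
                 threshold = x$threshold)
}

#' Glance at a sweep grid
#'
#' @param x A `sweep_grid`.
#' @param ... Unused.
#' @return A one-row tibble: grid dimensions, category shares, failure
#'   count.
#' @export
glance.sweep_grid <- function(x, ...) {
  df <- tibble::as_tibble(x)
  tibble::tibble(
    g_syn = attr(x, "g_syn"), i_app = attr(x, "i_app"),
    mode = attr(x, "mode"), n_cells = nrow(df),
    n_amplitudes = dplyr::n_distinct(df$A),
    n_frequencies = dplyr::n_distinct(df$omega0),
    frac_red = mean(df$category == "red", na.rm = TRUE),
    frac_matched = mean(df$matched, na.rm = TRUE),
    n_failed = sum(df$failed)
  )
}
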