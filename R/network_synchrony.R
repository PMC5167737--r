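# Whole-network synchrony via principal-component counting.

#' Count principal components capturing a variance threshold
#'
#' Covariance PCA (columns mean-centred, not rescaled) of the slow-variable
#' traces of all STN neurons. The synchrony score is the smallest number of
#' leading components whose cumulative variance fraction reaches the
#' threshold (80% in the study): fewer components means more coordinated
#' network activity.
#'
#' @param x Numeric matrix, samples by neurons (at least 2 rows).
#' @param threshold Cumulative variance fraction to capture.
#' @return A `synchrony_score`: `component_count`, ordered
#'   `variance_fractions` (descending eigenvalue fractions, summing to 1),
#'   `category` (see [classify_synchrony()]), `matched` (`NA` until combined
#'   with a transition-rate match).
#' @export
pca_component_count <- function(x, threshold = 0.8) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  total <- sum(ev)
  if (total <= 0) stop("degenerate input: zero total variance")
  frac <- ev / total
  count <- which(cumsum(frac) >= threshold - 1e-12)[1]
  # prcomp returns min(n - 1, p) components; pad with exact zeros
  if (length(frac) < ncol(x)) frac <- c(frac, rep(0, ncol(x) - length(frac)))
  structure(list(component_count = as.integer(count),
                 variance_fractions = frac,
                 category = classify_synchrony(count, n_max = ncol(x)),
                 matched = NA,
                 threshold = threshold),
            class = "synchrony_score")
}

#' @export
print.synchrony_score <- function(x, ...) {
  cat(sprintf("network synchrony: %d component(s) capture %.0f%% of variance (%s)\n",
              x$component_count, 100 * x$threshold, x$category))
  invisible(x)
}

#' Synchrony category from a component count
#'
#' The study's colour code for a 10-neuron population: 1-3 components `red`
#' (most synchronous), 4-5 `green`, 6-7 `blue`, 8-10 `black` (least
#' synchronous).
#'
#' @param count Integer component count in `1..n_max`.
#' @param n_max Number of neurons (upper bound of the count).
#' @return A character scalar.
#' @export
classify_synchrony <- function(count, n_max = 10L) {
  if (!is.finite(count) || count < 1 || count > n_max) {
    stop("component count out of range 1..", n_max)
  }
  if (count <= 3) "red" else if (count <= 5) "green"
  else if (count <= 7) "blue" else "black"
}

#' Slow-variable matrix of the STN population
#'
#' Post-transient traces of the configured slow variable (`r` by default;
#' `Ca` or the synaptic gate `s` selectable) for all STN neurons, as the
#' samples-by-neurons matrix fed to [pca_component_count()].
#'
#' @param sim A `stn_gpe_sim`.
#' @param which `"r"`, `"Ca"`, or `"s"`; `NULL` takes the configured value.
#' @return Numeric matrix, samples by STN neurons.
#' @export
slow_variable_matrix <- function(sim, which = NULL) {
  which <- which %||% sim$config$analysis$slow_variable
  idx <- analysis_window(sim)
  switch(which,
         r = sim$r_stn[idx, , drop = FALSE],
         Ca = sim$ca_stn[idx, , drop = FALSE],
         s = sim$s_stn[idx, , drop = FALSE],
         stop("slow variable must be 'r', 'Ca', or 's'"))
}

#' Network synchrony score of a simulation
#'
#' @param sim A `stn_gpe_sim`.
#' @param threshold Variance fraction; `NULL` takes the configured value.
#' @inheritParams slow_variable_matrix
#' @return A `synchrony_score`.
#' @export
network_synchrony <- function(sim, threshold = NULL, which = NULL) {
  threshold <- threshold %||% sim$config$analysis$pca_threshold
  pca_component_count(slow_variable_matrix(sim, which), threshold)
}
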