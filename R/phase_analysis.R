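# Temporal patterns of synchrony: beta-band filtering, Hilbert phase,
# first-return maps of the spike/LFP phase difference, region partitioning,
# transition rates, and the experiment-matching criterion.

#' Zero-phase beta-band filter
#'
#' Mean-removes the signal and applies a Butterworth band-pass forward and
#' backward (`signal::filtfilt`), so the output has no phase lag. The
#' effective magnitude response is the squared single-pass response.
#'
#' @param x Numeric signal on a uniform grid.
#' @param sample_rate Sampling rate in Hz.
#' @param band Pass band `c(low, high)` in Hz; the beta band here is
#'   10-30 Hz.
#' @param order Butterworth order of the single pass.
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_beta <- function(x, sample_rate, band = c(10, 30), order = 4) {
  min_len <- minimum_signal_length(sample_rate, band)
  if (length(x) < min_len) {
    stop("signal too short for stable band-pass filtering: need at least ",
         min_len, " samples at ", sample_rate, " Hz")
  }
  if (band[2] >= sample_rate / 2) stop("band upper edge must be below Nyquist")
  bf <- signal::butter(order, band / (sample_rate / 2), type = "pass")
  signal::filtfilt(bf, x - mean(x))
}

#' Instantaneous phase via the analytic signal
#'
#' Computes the discrete analytic signal by the FFT half-spectrum
#' construction (positive frequencies doubled, negative zeroed) and returns
#' its argument, wrapped to `(-pi, pi]`. For a pure tone at `f` Hz the
#' unwrapped phase advances at `2 pi f` per second; the phase is invariant
#' under positive rescaling of the signal.
#'
#' @param x Band-limited signal (typically the output of [bandpass_beta()]).
#' @param time Optional sample times (ms) carried through to the result.
#' @param source Label, e.g. `"lfp"` or `"spikes"`.
#' @return A `phase_series` object with fields `time`, `phase` (radians in
#'   `(-pi, pi]`), and `source`.
#' @export
instantaneous_phase <- function(x, time = NULL, source = "") {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  structure(list(time = time %||% seq_len(n), phase = Arg(z), source = source),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("phase series (%s): %d samples in (-pi, pi]\n",
              if (nzchar(x$source)) x$source else "unlabelled",
              length(x$phase)))
  invisible(x)
}

#' Beta-band phase of a simulated LFP or spike train
#'
#' Convenience extractors running the shared filter + analytic-signal chain
#' on a simulation: `lfp_phase()` on the surrogate LFP at a site,
#' `spike_phase()` on the binary spike train of one STN neuron (mean removed
#' before filtering). Only the post-transient analysis window is used.
#'
#' @param sim A `stn_gpe_sim`.
#' @param site,neuron STN index (1-based).
#' @param band Pass band in Hz; defaults to the configured beta band.
#' @return A `phase_series`.
#' @export
lfp_phase <- function(sim, site = 1, band = NULL) {
  band <- band %||% sim$config$analysis$beta_band
  idx <- analysis_window(sim)
  fs <- 1000 / sim$record_dt
  filt <- bandpass_beta(sim$lfp[idx, site], fs, band,
                        order = sim$config$analysis$filter_order)
  instantaneous_phase(filt, time = sim$time[idx], source = "lfp")
}

#' @rdname lfp_phase
#' @export
spike_phase <- function(sim, neuron = 1, band = NULL) {
  band <- band %||% sim$config$analysis$beta_band
  idx <- analysis_window(sim)
  fs <- 1000 / sim$record_dt
  filt <- bandpass_beta(sim$spike_train[idx, neuron], fs, band,
                        order = sim$config$analysis$filter_order)
  instantaneous_phase(filt, time = sim$time[idx], source = "spikes")
}

#' First-return map of the spike phase sampled once per LFP cycle
#'
#' Whenever the LFP phase crosses the checkpoint from negative to positive
#' (crossing instants located by linear interpolation between samples), the
#' spike-signal phase at that instant is recorded, giving the sequence
#' `phi_spikes[i]`, `i = 1..N` of once-per-cycle phase differences. The
#' numerical value of the checkpoint is irrelevant for locked signals.
#'
#' @param phi_lfp,phi_spikes `phase_series` on a common time grid.
#' @param checkpoint Crossing level in radians.
#' @return A `return_map_series` with fields `checkpoint`, `phi` (recorded
#'   phases, wrapped to `(-pi, pi]`), `times` (crossing instants, ms), and
#'   `n`.
#' @export
build_return_map <- function(phi_lfp, phi_spikes, checkpoint = 0) {
  if (length(phi_lfp$phase) != length(phi_spikes$phase)) {
    stop("phase series must share one time grid")
  }
  t <- phi_lfp$time
  pl <- phi_lfp$phase
  ps_un <- unwrap_phase(phi_spikes$phase)
  n <- length(pl)
  a <- pl[-n]; b <- pl[-1]
  cross <- which(a < checkpoint & b >= checkpoint & (b - a) < pi)
  if (length(cross) < 2L) {
    stop("fewer than 2 checkpoint crossings; analysis window too short")
  }
  frac <- (checkpoint - a[cross]) / (b[cross] - a[cross])
  tc <- t[cross] + frac * (t[cross + 1L] - t[cross])
  phi <- ps_un[cross] + frac * (ps_un[cross + 1L] - ps_un[cross])
  structure(list(checkpoint = checkpoint, phi = wrap_phase(phi), times = tc,
                 n = length(tc)),
            class = "return_map_series")
}

#' @export
print.return_map_series <- function(x, ...) {
  cat(sprintf("first-return map: %d crossings of checkpoint %.3g rad\n",
              x$n, x$checkpoint))
  invisible(x)
}

wrap_phase <- function(phi) {
  w <- (phi + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

unwrap_phase <- function(phi) {
  d <- diff(phi)
  jump <- cumsum(c(0, -round(d / (2 * pi)) * 2 * pi))
  phi + jump
}

circular_mean <- function(phi) {
  atan2(mean(sin(phi)), mean(cos(phi)))
}

#' Partition the first-return map into four regions
#'
#' Map points are the consecutive pairs `(phi[i], phi[i + 1])` on the torus.
#' The locked-state centre is the circular mean of the recorded phases; each
#' coordinate is "synchronized" when its circular distance to the centre is
#' below `pi / 2`. The four equal square regions are the quadrants relative
#' to the centre, numbered in order of traversal during a desynchronization
#' event: region 1 (both synchronized, the synchronization region), 2 (first
#' in, second out — leaving), 3 (both out), 4 (first out, second in —
#' returning).
#'
#' @param map A `return_map_series`.
#' @param center Optional locked-state centre (radians); by default the
#'   circular mean of the recorded phases.
#' @return A list with `labels` (integer 1..4 per map point, length
#'   `n - 1`), `center` (radians), and `sync_region` (always 1).
#' @export
partition_regions <- function(map, center = NULL) {
  phi <- map$phi
  if (length(phi) < 2L) stop("need at least 2 recorded phases")
  if (!is.null(center)) {
    inside <- abs(wrap_phase(phi - center)) < pi / 2
    a <- inside[-length(inside)]
    b <- inside[-1]
    labels <- ifelse(a & b, 1L, ifelse(a & !b, 2L, ifelse(!a & !b, 3L, 4L)))
    return(list(labels = as.integer(labels), center = center, sync_region = 1L))
  }
  R <- sqrt(mean(sin(phi))^2 + mean(cos(phi))^2)
  if (R < 1e-8) {
    # Perfectly uniform: fall back to the densest quartile of the circle.
    brk <- seq(-pi, pi, by = pi / 2)
    dens <- table(cut(phi, brk))
    center <- brk[which.max(dens)] + pi / 4
    message("circular mean undefined; using densest-quartile centre")
  } else {
    center <- circular_mean(phi)
  }
  inside <- abs(wrap_phase(phi - center)) < pi / 2
  a <- inside[-length(inside)]
  b <- inside[-1]
  labels <- ifelse(a & b, 1L, ifelse(a & !b, 2L, ifelse(!a & !b, 3L, 4L)))
  list(labels = as.integer(labels), center = center, sync_region = 1L)
}

#' Transition rates between return-map regions
#'
#' For each region, the number of map points leaving it (next point in a
#' different region) divided by the number of points in it. The final map
#' point has no successor and cannot leave; occupancies sum to the number of
#' map points.
#'
#' @param labels Integer region labels (1..4), e.g. from
#'   [partition_regions()].
#' @return A `transition_rates` tibble with columns `region`, `occupancy`,
#'   `leaves`, `rate` (`NA` for empty regions) and attribute `sync_region`.
#' @export
transition_rates <- function(labels) {
  if (length(labels) < 2L) stop("need at least 2 labelled points")
  m <- length(labels)
  out <- tibble::tibble(
    region = 1:4,
    occupancy = vapply(1:4, function(k) sum(labels == k), integer(1)),
    leaves = vapply(1:4, function(k) {
      sum(labels[-m] == k & labels[-1] != k)
    }, integer(1))
  )
  out$rate <- ifelse(out$occupancy > 0, out$leaves / out$occupancy, NA_real_)
  structure(out, class = c("transition_rates", class(out)), sync_region = 1L)
}

#' Experiment-matching criterion for transition rates
#'
#' The model dynamics is held similar to a reference (experimental)
#' recording when every region's transition rate lies within `k` reference
#' standard deviations of the reference rate (boundary inclusive). The
#' reference values are configuration: they come from patient recordings not
#' distributed with the package.
#'
#' @param reference_rates,reference_sds Numeric length-4 vectors.
#' @param k Tolerance multiplier (study value 0.7).
#' @return A `match_criterion` object.
#' @export
match_criterion <- function(reference_rates, reference_sds, k = 0.7) {
  if (length(reference_rates) != 4L || length(reference_sds) != 4L) {
    stop("reference rates and SDs must have length 4")
  }
  if (any(reference_sds <= 0)) stop("reference SDs must be > 0")
  if (k <= 0) stop("tolerance multiplier k must be > 0")
  structure(list(reference_rates = as.numeric(reference_rates),
                 reference_sds = as.numeric(reference_sds), k = k),
            class = "match_criterion")
}

#' @rdname match_criterion
#' @param rates A [transition_rates()] result.
#' @param criterion A `match_criterion`.
#' @return `matches_experiment()`: `TRUE` iff all four model rates are
#'   defined and within `k * SD` of the reference; `FALSE` otherwise (with a
#'   `reason` attribute when rates are missing).
#' @export
matches_experiment <- function(rates, criterion) {
  r <- rates$rate[order(rates$region)]
  if (anyNA(r)) {
    out <- FALSE
    attr(out, "reason") <- paste("undefined rate in region(s)",
                                 paste(which(is.na(r)), collapse = ", "))
    return(out)
  }
  all(abs(r - criterion$reference_rates) <=
        criterion$k * criterion$reference_sds + 1e-9)
}

#' Full synchrony-pattern analysis of one simulation
#'
#' Runs the chain LFP/spike beta phases -> first-return map -> region
#' partition -> transition rates -> experiment match for one (site, neuron)
#' pair.
#'
#' @param sim A `stn_gpe_sim`.
#' @param site LFP site (STN index).
#' @param neuron STN neuron whose spike train is analysed.
#' @param checkpoint LFP-phase crossing level (radians); `NULL` takes the
#'   configured value.
#' @param criterion A [match_criterion()]; `NULL` builds one from the
#'   configured reference values.
#' @return A list with `map`, `partition`, `rates`, and `matched`.
#' @export
synchrony_patterns <- function(sim, site = 1, neuron = 1, checkpoint = NULL,
                               criterion = NULL) {
  an <- sim$config$analysis
  checkpoint <- checkpoint %||% an$checkpoint
  criterion <- criterion %||% match_criterion(an$match$reference_rates,
                                              an$match$reference_sds,
                                              an$match$k)
  map <- build_return_map(lfp_phase(sim, site), spike_phase(sim, neuron),
                          checkpoint)
  part <- partition_regions(map)
  rates <- transition_rates(part$labels)
  list(map = map, partition = part, rates = rates,
       matched = matches_experiment(rates, criterion))
}
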