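# External input currents applied to the STN population, plus the synthetic
# broadband cortical-surrogate generator used in place of a recorded EEG.

#' Specify the external input current
#'
#' @param mode `"none"`, `"sine"` (pure tone `A sin(2 pi omega0 t / 1000)`,
#'   `t` in ms), `"noisy_sine"` (the same with an i.i.d. Gaussian phase
#'   jitter inside the argument), or `"phase_derived"` (the current
#'   `A sin(phi(t))` where `phi` is the beta-band Hilbert phase of a supplied
#'   signal).
#' @param A Amplitude in model current units (>= 0).
#' @param omega0 Input frequency in Hz (sine modes).
#' @param noise_variance Variance of the phase jitter (radians^2); the study
#'   value is 0.08.
#' @param seed Integer seed controlling the jitter realization.
#' @param source_signal A [sampled_signal()] (phase-derived mode only).
#' @param band Beta band (Hz) used to extract the phase in phase-derived
#'   mode.
#' @return An `input_spec` object.
#' @export
input_spec <- function(mode = c("none", "sine", "noisy_sine", "phase_derived"),
                       A = 0, omega0 = 13, noise_variance = 0.08, seed = 1L,
                       source_signal = NULL, band = c(10, 30)) {
  mode <- match.arg(mode)
  if (A < 0) stop("amplitude A must be >= 0")
  if (omega0 <= 0) stop("omega0 must be positive (Hz)")
  if (noise_variance < 0) stop("noise_variance must be >= 0")
  if (mode == "phase_derived" && is.null(source_signal)) {
    stop("phase_derived mode requires a source_signal")
  }
  structure(list(mode = mode, A = A, omega0 = omega0,
                 noise_variance = noise_variance, seed = as.integer(seed),
                 source_signal = source_signal, band = band),
            class = "input_spec")
}

#' @export
print.input_spec <- function(x, ...) {
  cat("external input:", x$mode)
  if (x$mode != "none") cat(sprintf(", A = %g", x$A))
  if (x$mode %in% c("sine", "noisy_sine")) cat(sprintf(", omega0 = %g Hz", x$omega0))
  if (x$mode == "noisy_sine") cat(sprintf(", jitter variance = %g", x$noise_variance))
  cat("\n")
  invisible(x)
}

#' Pure sinusoidal input current
#'
#' `A sin(2 pi omega0 t / 1000)` with `t` in ms and `omega0` in Hz, so the
#' period in ms is `1000 / omega0`.
#'
#' @param t Time(s) in ms (vectorized).
#' @param spec An [input_spec()] with `mode = "sine"` (or any spec; only `A`
#'   and `omega0` are used).
#' @return Current in model units, bounded by `A` in absolute value.
#' @export
sine_input <- function(t, spec) {
  spec$A * sin(2 * pi * spec$omega0 * t / 1000)
}

#' Phase-jittered sinusoidal input current
#'
#' `A sin(2 pi omega0 t / 1000 + xi_t)` with `xi_t` i.i.d. Gaussian of mean 0
#' and variance `spec$noise_variance`, drawn once per element of `t` from
#' `spec$seed` (the caller's RNG state is left untouched). The jitter widens
#' the spectral peak without moving it off `omega0`.
#'
#' @inheritParams sine_input
#' @param xi Optional pre-drawn jitter vector (recycled against `t`); when
#'   supplied no random numbers are generated.
#' @return Current in model units, bounded by `A` in absolute value.
#' @export
noisy_sine_input <- function(t, spec, xi = NULL) {
  if (is.null(xi)) {
    xi <- with_preserved_seed(spec$seed,
      stats::rnorm(length(t), 0, sqrt(spec$noise_variance)))
  }
  spec$A * sin(2 * pi * spec$omega0 * t / 1000 + xi)
}

#' Input current derived from the phase of a recorded or surrogate signal
#'
#' The signal is band-pass filtered (shared zero-phase beta filter,
#' [bandpass_beta()]), its instantaneous phase `phi(t)` extracted by the
#' Hilbert-transform analytic signal ([instantaneous_phase()]), and the
#' current `A sin(phi(t))` returned — a constant-amplitude current carrying
#' only the timing of the source's beta rhythm.
#'
#' @param signal A [sampled_signal()].
#' @param A Amplitude (model current units).
#' @param band Pass band in Hz.
#' @param times Optional time grid (ms) onto which the current is linearly
#'   interpolated, e.g. the integrator grid; `NULL` keeps the native grid.
#' @return A tibble with columns `time` (ms) and `current`.
#' @export
phase_derived_input <- function(signal, A, band = c(10, 30), times = NULL) {
  stopifnot(inherits(signal, "sampled_signal"))
  min_len <- minimum_signal_length(signal$sample_rate, band)
  if (length(signal$values) < min_len) {
    stop("signal too short for stable phase extraction: need at least ",
         min_len, " samples at ", signal$sample_rate, " Hz")
  }
  filt <- bandpass_beta(signal$values, signal$sample_rate, band)
  phi <- instantaneous_phase(filt)
  t_ms <- (seq_along(signal$values) - 1) / signal$sample_rate * 1000
  cur <- A * sin(phi$phase)
  if (!is.null(times)) {
    cur <- stats::approx(t_ms, cur, xout = times, rule = 2)$y
    t_ms <- times
  }
  tibble::tibble(time = t_ms, current = cur)
}

# Samples needed so filter edge transients stay clear of the analysis: three
# periods of the low band edge on each side.
minimum_signal_length <- function(sample_rate, band) {
  ceiling(6 * sample_rate / band[1])
}

#' Synthetic broadband cortical-surrogate signal
#'
#' Stands in for a scalp-EEG recording over motor cortex: Gaussian white
#' noise shaped by a second-order resonator centred at `peak_freq` (pole
#' radius set from `bandwidth`), mixed with a white floor so the spectrum
#' stays broadband, then normalized to unit variance. The smoothed
#' periodogram of a long realization peaks at `peak_freq` and retains
#' appreciable power across the 10-30 Hz beta band.
#'
#' @param peak_freq Spectral peak (Hz), default 13.
#' @param bandwidth Approximate -3 dB width of the resonance (Hz).
#' @param duration Length in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed; the same seed reproduces the signal exactly.
#' @param floor_sd Standard-deviation ratio of the white floor to the shaped
#'   component before normalization.
#' @return A [sampled_signal()].
#' @export
synthetic_cortical_signal <- function(peak_freq = 13, bandwidth = 8,
                                      duration = 60, sample_rate = 1000,
                                      seed = 1L, floor_sd = 0.3) {
  if (peak_freq <= 0 || peak_freq >= sample_rate / 2) {
    stop("peak_freq must lie in (0, sample_rate / 2)")
  }
  if (bandwidth <= 0) stop("bandwidth must be positive")
  n <- round(duration * sample_rate)
  white <- with_preserved_seed(seed, stats::rnorm(2L * n))
  # Second-order resonator: poles at radius rho; the pole angle is adjusted
  # so the magnitude response peaks exactly at peak_freq.
  rho <- exp(-pi * bandwidth / sample_rate)
  omega <- 2 * pi * peak_freq / sample_rate
  theta <- acos(pmin(1, pmax(-1, 2 * rho * cos(omega) / (1 + rho^2))))
  shaped <- stats::filter(white[seq_len(n)], c(2 * rho * cos(theta), -rho^2),
                          method = "recursive")
  shaped <- as.numeric(shaped) / stats::sd(shaped)
  x <- shaped + floor_sd * white[(n + 1L):(2L * n)]
  x <- (x - mean(x)) / stats::sd(x)
  sampled_signal(x, sample_rate,
                 label = sprintf("synthetic cortical surrogate (peak %g Hz)", peak_freq))
}

#' A sampled single-channel signal
#'
#' @param values Numeric samples.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param label Free-text description.
#' @return A `sampled_signal` object.
#' @export
sampled_signal <- function(values, sample_rate, label = "") {
  if (sample_rate <= 0) stop("sample_rate must be positive")
  structure(list(values = as.numeric(values), sample_rate = sample_rate,
                 label = label), class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("sampled signal: %d samples at %g Hz (%.2f s)%s\n",
              length(x$values), x$sample_rate,
              length(x$values) / x$sample_rate,
              if (nzchar(x$label)) paste0(" - ", x$label) else ""))
  invisible(x)
}

#' Read or write a sampled signal as columnar text
#'
#' Two layouts are supported and auto-detected on read: two numeric columns
#' `time_s value` (sample rate inferred from the time column), or a single
#' value column preceded by a header line `# sample_rate: <Hz>`.
#'
#' @param path File path.
#' @return A [sampled_signal()].
#' @export
read_sampled_signal <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^#\\s*sample_rate:", first)) {
    fs <- as.numeric(sub("^#\\s*sample_rate:\\s*", "", first))
    vals <- utils::read.table(path, comment.char = "#")[[1]]
    return(sampled_signal(vals, fs, label = basename(path)))
  }
  tab <- utils::read.table(path, comment.char = "#")
  if (ncol(tab) < 2L) stop("expected 'time_s value' columns or a '# sample_rate:' header")
  dt <- diff(tab[[1]])
  if (any(dt <= 0)) stop("time column must be strictly increasing")
  sampled_signal(tab[[2]], 1 / stats::median(dt), label = basename(path))
}

#' @rdname read_sampled_signal
#' @param signal A [sampled_signal()].
#' @param layout `"single"` (value column + sample-rate header) or
#'   `"two_column"` (`time_s value`).
#' @export
write_sampled_signal <- function(signal, path, layout = c("single", "two_column")) {
  layout <- match.arg(layout)
  if (layout == "single") {
    writeLines(c(sprintf("# sample_rate: %g", signal$sample_rate),
                 format(signal$values, digits = 10)), path)
  } else {
    t_s <- (seq_along(signal$values) - 1) / signal$sample_rate
    utils::write.table(data.frame(time_s = t_s, value = signal$values), path,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Evaluate an input specification at given times
#'
#' Deterministic evaluation used by [network_rhs()] and for auditing input
#' realizations. Noisy-sine specs accept a pre-drawn jitter (`xi`); if absent
#' the jitter is drawn reproducibly from `spec$seed`.
#'
#' @inheritParams noisy_sine_input
#' @return Current in model units at each `t`.
#' @export
input_current <- function(t, spec, xi = NULL) {
  switch(spec$mode,
    none = rep(0, length(t)),
    sine = sine_input(t, spec),
    noisy_sine = noisy_sine_input(t, spec, xi = xi),
    phase_derived = phase_derived_input(spec$source_signal, spec$A,
                                        spec$band, times = t)$current)
}

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
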