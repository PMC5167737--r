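# Time integration of the network, spike extraction, and surrogate LFPs.

#' Simulate the STN-GPe network
#'
#' Fixed-step RK4 integration of the full network (compiled core). Initial
#' conditions are drawn from the run seed: membrane potentials uniform on the
#' configured range, gating variables at their steady state for the initial
#' potential, calcium and synaptic gates at configured values. For
#' `noisy_sine` input the phase jitter is drawn per integrator step from the
#' same seed; results are bit-reproducible given `(config, input, seed)`.
#'
#' @param config Configuration list from [load_config()] /
#'   [default_config()].
#' @param input An [input_spec()]; the external current enters STN neurons
#'   only.
#' @param duration,dt,transient,record_dt Integration settings (ms);
#'   `NULL` takes the value from `config$integration`.
#' @param seed Integer seed for initial conditions and input noise.
#' @param g_syn,i_app Convenience overrides of the pallido-subthalamic
#'   conductance and the GPe applied current.
#' @return An object of class `stn_gpe_sim`: recorded `time` grid (ms),
#'   matrices `v_stn`, `v_gpe`, `r_stn`, `ca_stn`, `s_stn`, `s_gpe`,
#'   `isyn_stn` (inhibitory GPe-to-STN current onto each STN neuron), the
#'   recorded `input` current, per-STN-neuron `spikes` (times and binary
#'   trains), per-site `lfp` traces, and the config snapshot with the seed.
#' @export
simulate_network <- function(config = default_config(),
                             input = input_spec("none"),
                             duration = NULL, dt = NULL, transient = NULL,
                             record_dt = NULL, seed = 1L,
                             g_syn = NULL, i_app = NULL) {
  if (!is.null(g_syn)) config$synapse$gpe_to_stn$g_syn <- g_syn
  if (!is.null(i_app)) config$gpe$I_app <- i_app
  it <- config$integration
  duration <- duration %||% it$duration
  dt <- dt %||% it$dt
  transient <- transient %||% it$transient
  record_dt <- record_dt %||% it$record_dt
  if (dt <= 0) stop("dt must be positive")
  if (duration <= transient) stop("duration must exceed the transient")
  stride <- record_dt / dt
  if (abs(stride - round(stride)) > 1e-8) {
    stop("record_dt must be an integer multiple of dt")
  }
  stride <- as.integer(round(stride))
  n_steps <- as.integer(round(duration / dt))
  n <- config$topology$n_stn
  topo <- network_topology(n, config$topology$n_gpe)

  y0 <- with_preserved_seed(seed, initial_state(config, n))

  xi <- numeric(0); ext <- numeric(0); mode_code <- 0L
  if (input$mode == "sine") {
    mode_code <- 1L
  } else if (input$mode == "noisy_sine") {
    mode_code <- 2L
    xi <- with_preserved_seed(input$seed,
      stats::rnorm(n_steps, 0, sqrt(input$noise_variance)))
  } else if (input$mode == "phase_derived") {
    mode_code <- 3L
    step_t <- (seq_len(n_steps) - 1) * dt
    ext <- phase_derived_input(input$source_signal, input$A, input$band,
                               times = step_t)$current
  }

  raw <- rk4_integrate_cpp(y0, n, pack_cell(config$stn), pack_cell(config$gpe),
                           pack_syn(config$synapse$stn_to_gpe),
                           pack_syn(config$synapse$gpe_to_stn),
                           dt, n_steps, stride, mode_code,
                           input$A, input$omega0, xi, ext, 0.0)

  sim <- structure(list(
    time = raw$time, v_stn = raw$v_stn, v_gpe = raw$v_gpe,
    r_stn = raw$r_stn, ca_stn = raw$ca_stn, s_stn = raw$s_stn,
    s_gpe = raw$s_gpe, isyn_stn = raw$isyn_stn, input = raw$input,
    state_final = raw$state_final,
    dt = dt, record_dt = record_dt, duration = duration,
    transient = transient, seed = as.integer(seed),
    input_spec = input, config = config
  ), class = "stn_gpe_sim")

  thr <- it$spike_threshold
  refr <- it$refractory
  sim$spikes <- lapply(seq_len(n), function(i) {
    detect_spikes(sim$v_stn[, i], sim$time, threshold = thr, refractory = refr)
  })
  sim$spike_train <- vapply(sim$spikes, `[[`, numeric(length(sim$time)), "train")
  hw <- config$analysis$lfp_halfwidth
  w <- rep(1, hw + 1) / (2 * hw + 1)
  sim$lfp <- vapply(seq_len(n), function(i) compute_lfp(sim$isyn_stn, i, w),
                    numeric(length(sim$time)))
  sim
}

# Initial network state: v ~ U[v_min, v_max] per neuron, gates at steady
# state for the drawn v, Ca and s from config. Uses the current RNG stream.
initial_state <- function(config, n) {
  ic <- config$integration$initial_conditions
  mk <- function(p) {
    v <- stats::runif(n, ic$v_min, ic$v_max)
    cbind(v = v,
          n = xinf(v, p$curves$n_inf),
          h = xinf(v, p$curves$h_inf),
          r = xinf(v, p$curves$r_inf),
          Ca = rep(ic$Ca0, n))
  }
  stn <- mk(config$stn)
  gpe <- mk(config$gpe)
  pack_network_state(stn, gpe, rep(ic$s0, n), rep(ic$s0, n))
}

#' @export
print.stn_gpe_sim <- function(x, ...) {
  n <- ncol(x$v_stn)
  win <- x$duration - x$transient
  rates <- vapply(x$spikes, function(s) {
    sum(s$times > x$transient) / win * 1000
  }, numeric(1))
  cat(sprintf("STN-GPe simulation: %d + %d neurons, %.0f ms (%.0f ms transient), dt = %g ms\n",
              n, ncol(x$v_gpe), x$duration, x$transient, x$dt))
  cat(sprintf("  input: %s; seed %d\n", x$input_spec$mode, x$seed))
  cat(sprintf("  STN firing rate %.1f +/- %.1f Hz (post-transient)\n",
              mean(rates), stats::sd(rates)))
  invisible(x)
}

#' Indices of the analysis window (transient excluded)
#'
#' @param sim A `stn_gpe_sim`.
#' @return Integer indices into the recorded time grid with
#'   `time >= transient`.
#' @export
analysis_window <- function(sim) {
  which(sim$time >= sim$transient)
}

#' Detect spikes in a membrane-potential trace
#'
#' A spike is an upward crossing of `threshold`; crossings closer than
#' `refractory` to the previous accepted spike are ignored.
#'
#' @param v Membrane potential samples (mV) on a uniform grid.
#' @param time Sample times (ms), same length as `v`.
#' @param threshold Crossing level (mV).
#' @param refractory Minimal inter-spike separation (ms).
#' @return A list with `times` (ms of accepted crossings) and `train`
#'   (binary vector, 1 at spike samples).
#' @export
detect_spikes <- function(v, time, threshold = -20, refractory = 2) {
  n <- length(v)
  up <- which(v[-n] < threshold & v[-1] >= threshold) + 1L
  keep <- integer(0)
  last <- -Inf
  for (i in up) {
    if (time[i] - last >= refractory) {
      keep <- c(keep, i)
      last <- time[i]
    }
  }
  train <- numeric(n)
  train[keep] <- 1
  list(times = time[keep], train = train)
}

#' Surrogate local field potential at an STN site
#'
#' Weighted sum of the inhibitory synaptic input delivered to the site neuron
#' and its ring neighbours: `LFP_i(t) = sum_j w(d(i, j)) * I_syn_j(t)` with
#' `d` the ring distance and `w` supported on distances
#' `0 .. length(weights) - 1`. Linear in the synaptic inputs.
#'
#' @param isyn Matrix of per-neuron synaptic input traces (samples x
#'   neurons), e.g. `sim$isyn_stn`.
#' @param site Site neuron index (1-based).
#' @param weights Non-negative weights by ring distance; the default averages
#'   the site and its two nearest neighbours.
#' @return Numeric LFP trace.
#' @export
compute_lfp <- function(isyn, site, weights = c(1, 1) / 3) {
  n <- ncol(isyn)
  if (site < 1 || site > n) stop("site out of range 1..", n)
  if (any(weights < 0) || any(!is.finite(weights))) {
    stop("weights must be finite and non-negative")
  }
  lfp <- numeric(nrow(isyn))
  for (j in seq_len(n)) {
    d <- min(abs(j - site), n - abs(j - site))
    if (d + 1 <= length(weights) && weights[d + 1] > 0) {
      lfp <- lfp + weights[d + 1] * isyn[, j]
    }
  }
  lfp
}

#' Persist a simulation result
#'
#' Writes the full result as a single RDS container (slots as documented in
#' [simulate_network()]); [export_traces()] writes individual traces as
#' columnar text for audit.
#'
#' @param sim A `stn_gpe_sim`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  saveRDS(sim, path)
  invisible(path)
}

#' @rdname write_simulation
#' @export
read_simulation <- function(path) {
  sim <- readRDS(path)
  if (!inherits(sim, "stn_gpe_sim")) stop("not a stored stn_gpe_sim object")
  sim
}

#' @rdname write_simulation
#' @param dir Output directory (created if needed); one whitespace-separated
#'   text file per trace family (`time` column first).
#' @export
export_traces <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(mat, name) {
    df <- data.frame(time = sim$time, mat)
    utils::write.table(df, file.path(dir, paste0(name, ".txt")),
                       row.names = FALSE, quote = FALSE)
  }
  wr(sim$v_stn, "v_stn"); wr(sim$v_gpe, "v_gpe"); wr(sim$r_stn, "r_stn")
  wr(sim$s_stn, "s_stn"); wr(sim$s_gpe, "s_gpe"); wr(sim$lfp, "lfp")
  wr(sim$spike_train, "spike_train"); wr(sim$input, "input")
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
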