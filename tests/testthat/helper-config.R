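# Shared helpers: small, fast configurations and cached acceptance sweeps.

# Default configuration with all synapses silenced (isolated neurons).
uncoupled_config <- function() {
  cfg <- default_config()
  cfg$synapse$gpe_to_stn$g_syn <- 0
  cfg$synapse$stn_to_gpe$g_syn <- 0
  cfg
}

# Configuration with every conductance zero and no applied current: the
# membrane equation reduces to dv/dt = 0.
dead_config <- function() {
  cfg <- default_config()
  for (pop in c("stn", "gpe")) {
    for (g in c("g_Na", "g_K", "g_L", "g_Ca", "g_T", "g_AHP")) cfg[[pop]][[g]] <- 0
    cfg[[pop]]$I_app <- 0
  }
  cfg$synapse$gpe_to_stn$g_syn <- 0
  cfg$synapse$stn_to_gpe$g_syn <- 0
  cfg
}

# A valid random network state for RHS consistency checks.
random_state <- function(n = 10L, seed = 1L) {
  set.seed(seed)
  mk <- function() cbind(v = runif(n, -80, 20), n = runif(n), h = runif(n),
                         r = runif(n), Ca = runif(n, 0, 2))
  pack_network_state(mk(), mk(), runif(n), runif(n))
}

# The scaled-down acceptance sweep protocol (sine input, 14-24 Hz x A 0-10,
# 6 s cells with 1 s transient, 3 replicate seeds, median aggregation).
# Cached per preset so several tests can share one run.
.sweep_cache <- new.env(parent = emptyenv())
acceptance_sweep <- function(preset, seed = 20260922L) {
  key <- paste(preset, seed)
  if (is.null(.sweep_cache[[key]])) {
    .sweep_cache[[key]] <- run_sweep(
      preset = preset, mode = "sine", amplitudes = 0:10, frequencies = 14:24,
      duration = 6000, transient = 1000, replicates = 3L, seed = seed,
      rates = FALSE, early_stop_count = 3L
    )
  }
  .sweep_cache[[key]]
}
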