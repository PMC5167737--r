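#' Load the default network configuration
#'
#' Reads the parameter file shipped with the package. Every model constant —
#' cell conductances and reversal potentials, gating-curve midpoints and
#' slopes, synapse kinetics, topology, integration and analysis settings —
#' lives in this file; nothing is hard-coded elsewhere.
#'
#' @return A nested list with sections `stn`, `gpe`, `synapse`, `topology`,
#'   `integration`, and `analysis`.
#' @seealso [load_config()] to read a user file or override entries.
#' @export
default_config <- function() {
  path <- system.file("extdata", "default_parameters.yaml", package = "stngpe")
  if (path == "") stop("default parameter file not found in installed package")
  load_config(path)
}

#' Load a network configuration file
#'
#' @param path Path to a YAML configuration with the same layout as the
#'   shipped default (see [default_config()]). `NULL` loads the default.
#' @param overrides Named nested list merged over the file contents, e.g.
#'   `list(gpe = list(I_app = 7))`.
#' @param g_syn,i_app Convenience overrides for the two study parameters:
#'   `g_syn` scales the pallido-subthalamic (GPe to STN) conductance and
#'   `i_app` the constant current applied to GPe neurons.
#' @return A validated configuration list.
#' @export
load_config <- function(path = NULL, overrides = list(), g_syn = NULL,
                        i_app = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_parameters.yaml",
                        package = "stngpe")
  }
  cfg <- yaml::read_yaml(path)
  if (length(overrides)) cfg <- utils::modifyList(cfg, overrides)
  if (!is.null(g_syn)) cfg$synapse$gpe_to_stn$g_syn <- g_syn
  if (!is.null(i_app)) cfg$gpe$I_app <- i_app
  validate_config(cfg)
}

#' Write a configuration to a YAML file
#'
#' @param config A configuration list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

validate_config <- function(cfg) {
  for (sec in c("stn", "gpe", "synapse", "topology", "integration",
                "analysis")) {
    if (is.null(cfg[[sec]])) stop("configuration is missing section '", sec, "'")
  }
  cfg$stn <- neuron_parameters(cfg$stn)
  cfg$gpe <- neuron_parameters(cfg$gpe)
  cfg$synapse$stn_to_gpe <- synapse_parameters(cfg$synapse$stn_to_gpe)
  cfg$synapse$gpe_to_stn <- synapse_parameters(cfg$synapse$gpe_to_stn)
  top <- cfg$topology
  if (top$n_stn != top$n_gpe) {
    stop("ring topology requires equal STN and GPe counts")
  }
  it <- cfg$integration
  if (it$dt <= 0) stop("integration dt must be positive")
  if (it$record_dt < it$dt) stop("record_dt must be >= dt")
  if (it$duration <= it$transient) stop("duration must exceed transient")
  an <- cfg$analysis
  if (length(an$beta_band) != 2L || an$beta_band[1] >= an$beta_band[2]) {
    stop("analysis$beta_band must be an increasing pair of frequencies (Hz)")
  }
  if (!an$slow_variable %in% c("r", "Ca", "s")) {
    stop("analysis$slow_variable must be one of 'r', 'Ca', 's'")
  }
  cfg
}

#' Neuron parameter set
#'
#' Validates a single-cell parameter list (STN or GPe flavour of the same
#' conductance-based model) and attaches the `neuron_parameters` class.
#' Required fields: membrane capacitance `C`; maximal conductances `g_Na`,
#' `g_K`, `g_L`, `g_Ca`, `g_T`, `g_AHP`; reversal potentials `v_Na`, `v_K`,
#' `v_L`, `v_Ca`; calcium constants `k1`, `epsilon`, `k_Ca`; gating rate
#' scales `phi_n`, `phi_h`, `phi_r`; applied current `I_app`; T-current
#' inactivation mode `t_gate`; and the `curves` block of sigmoid
#' midpoints/slopes for the steady-state and time-constant functions.
#'
#' @param x A named list of parameter values.
#' @return The validated list, classed `neuron_parameters`.
#' @export
neuron_parameters <- function(x) {
  need <- c("C", "g_Na", "v_Na", "g_K", "v_K", "g_L", "v_L", "g_Ca", "g_T",
            "v_Ca", "g_AHP", "v_AHP", "k1", "epsilon", "k_Ca", "phi_n",
            "phi_h", "phi_r", "I_app", "t_gate", "curves", "cell_class")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("neuron parameters missing: ", paste(miss, collapse = ", "))
  gs <- c("g_Na", "g_K", "g_L", "g_Ca", "g_T", "g_AHP")
  if (any(unlist(x[gs]) < 0)) stop("conductances must be >= 0")
  if (x$C <= 0) stop("capacitance C must be > 0")
  if (x$epsilon <= 0) stop("epsilon must be > 0")
  if (x$k1 <= 0) stop("k1 must be > 0")
  if (!x$t_gate %in% c("b_sigmoid", "linear_r")) {
    stop("t_gate must be 'b_sigmoid' or 'linear_r'")
  }
  if (!toupper(x$cell_class) %in% c("STN", "GPE")) {
    stop("cell_class must be 'STN' or 'GPe'")
  }
  curves <- c("m_inf", "h_inf", "n_inf", "r_inf", "a_inf", "s_inf", "b_inf",
              "tau_n", "tau_h", "tau_r")
  miss <- setdiff(curves, names(x$curves))
  if (length(miss)) stop("gating curves missing: ", paste(miss, collapse = ", "))
  structure(x, class = "neuron_parameters")
}

#' Synapse parameter set
#'
#' Validates the kinetic and conductance parameters of one projection class
#' (first-order channel activation `ds/dt = alpha H(v_pre - theta_g) (1 - s)
#' - beta s` with sigmoidal `H`), and attaches the `synapse_parameters`
#' class.
#'
#' @param x A named list with fields `alpha`, `beta`, `theta_g`, `Theta_gH`,
#'   `sigma_gH`, `g_syn`, `v_syn`, `polarity`.
#' @return The validated list, classed `synapse_parameters`.
#' @export
synapse_parameters <- function(x) {
  need <- c("alpha", "beta", "theta_g", "Theta_gH", "sigma_gH", "g_syn",
            "v_syn", "polarity")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("synapse parameters missing: ", paste(miss, collapse = ", "))
  if (x$alpha <= 0 || x$beta <= 0) stop("alpha and beta must be > 0")
  if (x$sigma_gH == 0) stop("sigma_gH must be nonzero")
  if (x$g_syn < 0) stop("g_syn must be >= 0")
  if (!x$polarity %in% c("excitatory", "inhibitory")) {
    stop("polarity must be 'excitatory' or 'inhibitory'")
  }
  structure(x, class = "synapse_parameters")
}

#' Ring topology of the STN-GPe network
#'
#' Each STN neuron projects to the like-indexed GPe neuron; each GPe neuron
#' projects back to the like-indexed STN neuron and its two ring neighbours
#' (indices taken modulo `n`). Every STN neuron therefore receives exactly 3
#' GPe afferents and every GPe neuron exactly 1 STN afferent.
#'
#' @param n_stn,n_gpe Neuron counts (must be equal; default 10 each).
#' @return A `network_topology` object with adjacency lists `stn_to_gpe`
#'   (length `n_gpe`, one source each) and `gpe_to_stn` (length `n_stn`,
#'   three sources each).
#' @export
network_topology <- function(n_stn = 10L, n_gpe = n_stn) {
  n_stn <- as.integer(n_stn); n_gpe <- as.integer(n_gpe)
  if (n_stn != n_gpe) stop("ring topology requires n_stn == n_gpe")
  if (n_stn < 3L) stop("ring topology needs at least 3 neurons per population")
  ring <- function(i) ((i - 1L) %% n_stn) + 1L
  structure(list(
    n_stn = n_stn,
    n_gpe = n_gpe,
    stn_to_gpe = lapply(seq_len(n_gpe), function(i) i),
    gpe_to_stn = lapply(seq_len(n_stn), function(i) ring(c(i - 1L, i, i + 1L)))
  ), class = "network_topology")
}

#' @export
print.network_topology <- function(x, ...) {
  cat("STN-GPe ring topology:", x$n_stn, "STN +", x$n_gpe, "GPe neurons\n")
  cat("  STN i -> GPe i; GPe i -> STN {i-1, i, i+1} (mod n)\n")
  invisible(x)
}

# Flatten cell parameters into the fixed-order numeric vector consumed by the
# compiled right-hand side. Order must match cell_param_index in src/.
pack_cell <- function(p) {
  cv <- p$curves
  c(p$C, p$g_Na, p$v_Na, p$g_K, p$v_K, p$g_L, p$v_L, p$g_Ca, p$g_T, p$v_Ca,
    p$g_AHP, p$v_AHP, p$k1, p$epsilon, p$k_Ca, p$phi_n, p$phi_h, p$phi_r,
    p$I_app,
    if (p$t_gate == "linear_r") 1 else 0,
    cv$m_inf$theta, cv$m_inf$sigma, cv$h_inf$theta, cv$h_inf$sigma,
    cv$n_inf$theta, cv$n_inf$sigma, cv$r_inf$theta, cv$r_inf$sigma,
    cv$a_inf$theta, cv$a_inf$sigma, cv$s_inf$theta, cv$s_inf$sigma,
    cv$b_inf$theta, cv$b_inf$sigma,
    cv$tau_n$tau0, cv$tau_n$tau1, cv$tau_n$theta, cv$tau_n$sigma,
    cv$tau_h$tau0, cv$tau_h$tau1, cv$tau_h$theta, cv$tau_h$sigma,
    cv$tau_r$tau0, cv$tau_r$tau1, cv$tau_r$theta, cv$tau_r$sigma)
}

pack_syn <- function(p) {
  c(p$alpha, p$beta, p$theta_g, p$Theta_gH, p$sigma_gH, p$g_syn, p$v_syn)
}
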