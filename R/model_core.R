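# Pure-R definition of the membrane model. The compiled integrator in src/
# implements the same equations; these functions are the readable reference,
# exposed for inspection and used by the tests as one side of the
# implementation/oracle cross-checks.

sigmoid <- function(x, theta, sigma) 1 / (1 + exp(-(x - theta) / sigma))

xinf <- function(v, curve) sigmoid(v, curve$theta, curve$sigma)

taux <- function(v, curve) curve$tau0 + curve$tau1 * sigmoid(v, curve$theta, curve$sigma)

binf <- function(r, curve) {
  sigmoid(r, curve$theta, curve$sigma) - sigmoid(0, curve$theta, curve$sigma)
}

#' Single ionic membrane current
#'
#' Evaluates one of the six membrane currents of the model neuron:
#' \deqn{I_{Na} = g_{Na} m_\infty^3(v)\, h\, (v - v_{Na})}
#' \deqn{I_K = g_K n^4 (v - v_K)}
#' \deqn{I_L = g_L (v - v_L)}
#' \deqn{I_{Ca} = g_{Ca} s_\infty^2(v) (v - v_{Ca})}
#' \deqn{I_T = g_T a_\infty^3(v)\, b_\infty^2(r)\, (v - v_{Ca})}
#' \deqn{I_{AHP} = g_{AHP} \frac{[Ca]}{[Ca] + k_1} (v - v_{AHP})}
#' The afterhyperpolarization current is the calcium-activated
#' voltage-independent potassium current, so its reversal `v_AHP` defaults to
#' the potassium reversal.
#' For cells configured with `t_gate = "linear_r"` the T-current inactivation
#' factor is `r` itself instead of \eqn{b_\infty^2(r)}.
#'
#' @param kind One of `"Na"`, `"K"`, `"L"`, `"Ca"`, `"T"`, `"AHP"`.
#' @param state Named list or vector with `v` (mV), gating variables `n`,
#'   `h`, `r`, and calcium `Ca`.
#' @param params A [neuron_parameters()] object.
#' @return The current in model units (positive = outward under the sign
#'   convention of the membrane equation).
#' @export
ionic_current <- function(kind, state, params) {
  st <- as.list(state)
  vals <- unlist(st[c("v", "n", "h", "r", "Ca")])
  if (any(!is.finite(vals))) stop("non-finite neuron state")
  v <- st$v
  cv <- params$curves
  switch(kind,
    Na  = params$g_Na * xinf(v, cv$m_inf)^3 * st$h * (v - params$v_Na),
    K   = params$g_K * st$n^4 * (v - params$v_K),
    L   = params$g_L * (v - params$v_L),
    Ca  = params$g_Ca * xinf(v, cv$s_inf)^2 * (v - params$v_Ca),
    T   = {
      tg <- if (identical(params$t_gate, "linear_r")) st$r else binf(st$r, cv$b_inf)^2
      params$g_T * xinf(v, cv$a_inf)^3 * tg * (v - params$v_Ca)
    },
    AHP = params$g_AHP * (st$Ca / (st$Ca + params$k1)) * (v - params$v_AHP),
    stop("unknown current kind '", kind, "'")
  )
}

#' Gating-variable derivative
#'
#' First-order relaxation of a gating variable toward its voltage-dependent
#' steady state: \eqn{dx/dt = \phi_x (x_\infty(v) - x) / \tau_x(v)}.
#'
#' @param x Current gating value in \[0, 1\].
#' @param v Membrane potential (mV).
#' @param curve One of `"n"`, `"h"`, `"r"`.
#' @param params A [neuron_parameters()] object.
#' @return Rate of change (1/ms).
#' @export
gating_derivative <- function(x, v, curve = c("n", "h", "r"), params) {
  curve <- match.arg(curve)
  ss <- params$curves[[paste0(curve, "_inf")]]
  tc <- params$curves[[paste0("tau_", curve)]]
  phi <- params[[paste0("phi_", curve)]]
  tau <- taux(v, tc)
  if (tau <= 0) stop("non-positive time constant tau_", curve, "(v); check curve parameters")
  phi * (xinf(v, ss) - x) / tau
}

#' Intracellular calcium balance
#'
#' \eqn{d[Ca]/dt = \epsilon(-I_{Ca} - I_T - k_{Ca} [Ca])}: influx through the
#' two calcium currents (inward currents are negative, hence the signs)
#' balanced by first-order extrusion.
#'
#' @inheritParams ionic_current
#' @return Rate of change of `[Ca]` (model concentration units per ms).
#' @export
calcium_derivative <- function(state, params) {
  ica <- ionic_current("Ca", state, params)
  it <- ionic_current("T", state, params)
  params$epsilon * (-ica - it - params$k_Ca * as.list(state)$Ca)
}

#' Synaptic gate derivative
#'
#' Fraction of open channels at a synapse driven by the presynaptic
#' potential: \eqn{ds/dt = \alpha H_\infty(v_{pre} - \theta_g)(1 - s) -
#' \beta s} with \eqn{H_\infty(v) = 1/[1 + \exp(-(v - \Theta_g^H) /
#' \sigma_g^H)]}.
#'
#' @param s Gate value in \[0, 1\].
#' @param v_pre Presynaptic membrane potential (mV).
#' @param params A [synapse_parameters()] object.
#' @return Rate of change (1/ms).
#' @export
synaptic_gate_derivative <- function(s, v_pre, params) {
  H <- sigmoid(v_pre - params$theta_g, params$Theta_gH, params$sigma_gH)
  params$alpha * H * (1 - s) - params$beta * s
}

#' Total synaptic current onto a neuron
#'
#' \eqn{I_{syn} = g_{syn} (v - v_{syn}) \sum_j s_j} summed over the gates of
#' all afferent synapses of one projection class.
#'
#' @param v_post Postsynaptic membrane potential (mV).
#' @param gates Numeric vector of afferent gate values in \[0, 1\].
#' @param params A [synapse_parameters()] object.
#' @return Synaptic current in model units.
#' @export
synaptic_current <- function(v_post, gates, params) {
  params$g_syn * (v_post - params$v_syn) * sum(gates)
}

# Derivative of one neuron's five state variables given its total synaptic
# and external input currents.
neuron_rhs <- function(state, params, i_syn = 0, i_ext = 0) {
  st <- as.list(state)
  i_ion <- sum(vapply(c("Na", "K", "L", "Ca", "T", "AHP"),
                      ionic_current, numeric(1), state = state, params = params))
  c(v = (-i_ion + params$I_app - i_syn + i_ext) / params$C,
    n = gating_derivative(st$n, st$v, "n", params),
    h = gating_derivative(st$h, st$v, "h", params),
    r = gating_derivative(st$r, st$v, "r", params),
    Ca = calcium_derivative(state, params))
}

#' Full network right-hand side
#'
#' Assembles the derivative of the complete network state: for every STN
#' neuron \eqn{C \, dv/dt = -\sum I_{ionic} + I_{app} - I_{syn} + I_{STN}(t)}
#' (the external current enters STN cells only), the same without
#' \eqn{I_{STN}} for GPe neurons, plus all gating, calcium, and synaptic-gate
#' kinetics. STN neurons are inhibited by the gates of their three GPe
#' afferents; each GPe neuron is excited by its single STN afferent.
#'
#' @param state Numeric state vector in the layout produced by
#'   [pack_network_state()]: per-population blocks `v`, `n`, `h`, `r`, `Ca`
#'   (STN then GPe), then the STN-to-GPe gates, then the GPe-to-STN gates.
#' @param t Time (ms), used to evaluate the external input.
#' @param config Configuration list (see [load_config()]).
#' @param topology A [network_topology()] object.
#' @param input An [input_spec()]; evaluated deterministically, so noisy
#'   modes must carry a pre-drawn jitter via their realization (see
#'   [input_current()]).
#' @return Numeric derivative vector of the same length and layout.
#' @export
network_rhs <- function(state, t, config, topology = network_topology(config$topology$n_stn),
                        input = input_spec("none")) {
  n <- topology$n_stn
  if (length(state) != 12L * n) {
    stop("state has length ", length(state), ", expected ", 12L * n)
  }
  s <- unpack_network_state(state, n)
  syn_sg <- config$synapse$stn_to_gpe
  syn_gs <- config$synapse$gpe_to_stn
  i_ext <- input_current(t, input)

  proto <- c(v = 0, n = 0, h = 0, r = 0, Ca = 0)
  d_stn <- vapply(seq_len(n), function(i) {
    gates <- s$s_gpe[topology$gpe_to_stn[[i]]]
    isyn <- synaptic_current(s$stn[i, "v"], gates, syn_gs)
    neuron_rhs(s$stn[i, ], config$stn, i_syn = isyn, i_ext = i_ext)
  }, proto)
  d_gpe <- vapply(seq_len(n), function(i) {
    gates <- s$s_stn[topology$stn_to_gpe[[i]]]
    isyn <- synaptic_current(s$gpe[i, "v"], gates, syn_sg)
    neuron_rhs(s$gpe[i, ], config$gpe, i_syn = isyn)
  }, proto)
  d_s_stn <- vapply(seq_len(n), function(i) {
    synaptic_gate_derivative(s$s_stn[i], s$stn[i, "v"], syn_sg)
  }, numeric(1))
  d_s_gpe <- vapply(seq_len(n), function(i) {
    synaptic_gate_derivative(s$s_gpe[i], s$gpe[i, "v"], syn_gs)
  }, numeric(1))

  c(d_stn["v", ], d_stn["n", ], d_stn["h", ], d_stn["r", ], d_stn["Ca", ],
    d_gpe["v", ], d_gpe["n", ], d_gpe["h", ], d_gpe["r", ], d_gpe["Ca", ],
    d_s_stn, d_s_gpe)
}

#' Pack and unpack the network state vector
#'
#' The state layout is, for `n` neurons per population: STN blocks `v`, `n`,
#' `h`, `r`, `Ca` (each length `n`), the same five GPe blocks, then the `n`
#' STN-to-GPe synaptic gates and the `n` GPe-to-STN gates — `12 n` values in
#' total.
#'
#' @param stn,gpe Matrices `n x 5` with columns `v`, `n`, `h`, `r`, `Ca`.
#' @param s_stn,s_gpe Gate vectors of length `n`.
#' @return `pack_network_state()` returns the flat numeric vector;
#'   `unpack_network_state()` its inverse as a list.
#' @export
pack_network_state <- function(stn, gpe, s_stn, s_gpe) {
  c(stn[, "v"], stn[, "n"], stn[, "h"], stn[, "r"], stn[, "Ca"],
    gpe[, "v"], gpe[, "n"], gpe[, "h"], gpe[, "r"], gpe[, "Ca"],
    s_stn, s_gpe)
}

#' @rdname pack_network_state
#' @param state Flat state vector of length `12 n`.
#' @param n Neurons per population.
#' @export
unpack_network_state <- function(state, n) {
  block <- function(k) state[((k - 1L) * n + 1L):(k * n)]
  mk <- function(k0) {
    m <- cbind(v = block(k0), n = block(k0 + 1L), h = block(k0 + 2L),
               r = block(k0 + 3L), Ca = block(k0 + 4L))
    m
  }
  list(stn = mk(1L), gpe = mk(6L), s_stn = block(11L), s_gpe = block(12L))
}
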