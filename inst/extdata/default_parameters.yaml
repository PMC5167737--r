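# Default parameter file for the STN-GPe network model.
#
# Every model constant lives here; the package code never hard-codes any of
# these values.  The cell and synapse parameters are the canonical
# Terman-type subthalamo-pallidal set.  Sigmoid convention throughout:
#   sig(x; theta, sigma) = 1 / (1 + exp(-(x - theta) / sigma))
# so a negative sigma gives a decreasing curve.  Time constants:
#   tau_x(v) = tau0 + tau1 * sig(v; theta, sigma)
# b_inf is a sigmoid of the gating variable r, offset so that b_inf(0) = 0:
#   b_inf(r) = sig(r; theta_b, sigma_b) - sig(0; theta_b, sigma_b)
# t_gate selects the T-current inactivation factor: "b_sigmoid" uses
# b_inf(r)^2 (STN), "linear_r" uses r itself (GPe).
#
# Units: time ms, potential mV, conductance and current in model units,
# calcium in model concentration units.

stn:
  cell_class: STN
  C: 1.0
  g_Na: 37.5
  v_Na: 55.0
  g_K: 45.0
  v_K: -80.0
  g_L: 2.25
  v_L: -60.0
  g_Ca: 0.5
  g_T: 1.5
  v_Ca: 140.0
  g_AHP: 9.0
  v_AHP: -80.0   # reversal of the Ca-activated K current
  k1: 15.0
  epsilon: 5.0e-5
  k_Ca: 22.5
  phi_n: 0.75
  phi_h: 0.75
  phi_r: 0.5
  I_app: 19.8
  t_gate: b_sigmoid
  curves:
    m_inf: {theta: -30.0, sigma: 15.0}
    h_inf: {theta: -39.0, sigma: -3.1}
    n_inf: {theta: -32.0, sigma: 8.0}
    r_inf: {theta: -67.0, sigma: -2.0}
    a_inf: {theta: -63.0, sigma: 7.8}
    s_inf: {theta: -39.0, sigma: 8.0}
    b_inf: {theta: 0.25, sigma: 0.07}
    tau_n: {tau0: 1.0, tau1: 100.0, theta: -80.0, sigma: -26.0}
    tau_h: {tau0: 1.0, tau1: 500.0, theta: -57.0, sigma: -3.0}
    tau_r: {tau0: 7.1, tau1: 17.5, theta: -68.0, sigma: -2.2}

gpe:
  cell_class: GPe
  C: 1.0
  g_Na: 120.0
  v_Na: 55.0
  g_K: 30.0
  v_K: -80.0
  g_L: 1.0
  v_L: -63.0
  g_Ca: 0.15
  g_T: 0.5
  v_Ca: 120.0
  g_AHP: 30.0
  v_AHP: -80.0
  k1: 10.0
  epsilon: 5.0e-4
  k_Ca: 15.0
  phi_n: 0.05
  phi_h: 0.05
  phi_r: 1.0
  I_app: 5.0
  t_gate: linear_r
  curves:
    m_inf: {theta: -37.0, sigma: 10.0}
    h_inf: {theta: -58.0, sigma: -12.0}
    n_inf: {theta: -50.0, sigma: 14.0}
    r_inf: {theta: -70.0, sigma: -2.0}
    a_inf: {theta: -57.0, sigma: 2.0}
    s_inf: {theta: -35.0, sigma: 2.0}
    b_inf: {theta: 0.25, sigma: 0.07}  # unused under t_gate: linear_r
    tau_n: {tau0: 0.05, tau1: 0.27, theta: -40.0, sigma: -12.0}
    tau_h: {tau0: 0.05, tau1: 0.27, theta: -40.0, sigma: -12.0}
    tau_r: {tau0: 30.0, tau1: 0.0, theta: 0.0, sigma: 1.0}

synapse:
  # STN -> GPe: fast excitatory (AMPA-like) kinetics.
  stn_to_gpe:
    polarity: excitatory
    alpha: 5.0
    beta: 1.0
    theta_g: 30.0
    Theta_gH: -39.0
    sigma_gH: 8.0
    g_syn: 0.3
    v_syn: 0.0
  # GPe -> STN: slower inhibitory (GABA-A-like) kinetics.  g_syn here is the
  # pallido-subthalamic strength varied across study presets.
  gpe_to_stn:
    polarity: inhibitory
    alpha: 3.0
    beta: 0.07
    theta_g: 30.0
    Theta_gH: -39.0
    sigma_gH: 8.0
    g_syn: 0.9
    v_syn: -85.0

topology:
  n_stn: 10
  n_gpe: 10

integration:
  dt: 0.05            # ms, RK4 step
  record_dt: 0.25     # ms, sampling interval of stored traces (4 kHz)
  duration: 21000.0   # ms, total simulated time
  transient: 1000.0   # ms, discarded from all analyses
  spike_threshold: -20.0  # mV, upward crossing defines a spike
  refractory: 2.0     # ms, minimal inter-spike separation
  initial_conditions:
    v_min: -65.0      # mV, uniform draw
    v_max: -55.0
    Ca0: 0.3
    s0: 0.0

analysis:
  beta_band: [10.0, 30.0]  # Hz
  filter_order: 4          # Butterworth order (applied forward-backward)
  pca_threshold: 0.8
  slow_variable: r         # one of r, Ca, s
  lfp_halfwidth: 1         # ring neighbours on each side entering the LFP
  checkpoint: 0.0          # rad, LFP-phase crossing level
  match:
    k: 0.7
    # Placeholder reference transition rates and SDs; the experimental values
    # are not distributed with the package and must be supplied by the user.
    reference_rates: [0.31, 0.74, 0.46, 0.75]
    reference_sds: [0.10, 0.10, 0.10, 0.10]
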