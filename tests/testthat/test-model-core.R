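cfg <- default_config()
stn <- cfg$stn
gpe <- cfg$gpe

state0 <- list(v = -60, n = 0.5, h = 0.5, r = 0.5, Ca = 0.3)

test_that("ionic currents match closed-form values", {
  # zero gating annihilates the potassium current
  expect_equal(ionic_current("K", modifyList(state0, list(n = 0)), stn), 0)
  # leak vanishes at its reversal potential
  expect_equal(ionic_current("L", modifyList(state0, list(v = stn$v_L)), stn), 0)
  # AHP at calcium half-saturation: (g_AHP / 2) (v - v_AHP)
  st <- modifyList(state0, list(Ca = stn$k1))
  expect_equal(ionic_current("AHP", st, stn),
               stn$g_AHP / 2 * (state0$v - stn$v_AHP))
  # hand arithmetic: g_K = 45, n = 0.5, v = -60, v_K = -80
  p <- stn; p$g_K <- 45; p$v_K <- -80
  expect_equal(ionic_current("K", modifyList(state0, list(n = 0.5, v = -60)), p),
               45 * 0.5^4 * 20)
  expect_equal(45 * 0.5^4 * 20, 56.25)
})

test_that("every current is zero at its reversal potential", {
  for (p in list(stn, gpe)) {
    for (kind in c("Na", "K", "L")) {
      vr <- switch(kind, Na = p$v_Na, K = p$v_K, L = p$v_L)
      expect_equal(ionic_current(kind, modifyList(state0, list(v = vr)), p), 0)
    }
    for (kind in c("Ca", "T")) {
      expect_equal(ionic_current(kind, modifyList(state0, list(v = p$v_Ca)), p), 0)
    }
    expect_equal(ionic_current("AHP", modifyList(state0, list(v = p$v_AHP)), p), 0)
  }
})

test_that("invalid states and kinds are rejected", {
  expect_error(ionic_current("K", modifyList(state0, list(v = NaN)), stn),
               "non-finite")
  expect_error(ionic_current("Kv", state0, stn), "unknown current")
})

test_that("gating derivatives vanish at steady state and have the right sign", {
  for (curve in c("n", "h", "r")) {
    ss <- stn$curves[[paste0(curve, "_inf")]]
    for (v in c(-80, -60, -40)) {
      xin <- stngpe:::xinf(v, ss)
      expect_equal(gating_derivative(xin, v, curve, stn), 0, tolerance = 1e-12)
      expect_gt(gating_derivative(0, v, curve, stn), 0)
      expect_lt(gating_derivative(1, v, curve, stn), 0)
    }
  }
})

test_that("calcium balance reduces to pure decay without calcium currents", {
  # both Ca currents vanish at v = v_Ca
  st <- modifyList(state0, list(v = stn$v_Ca, Ca = 0.7))
  expect_equal(calcium_derivative(st, stn),
               -stn$epsilon * stn$k_Ca * 0.7)
  expect_equal(calcium_derivative(modifyList(st, list(Ca = 0)), stn), 0)
  # inward (negative) Ca currents at Ca = 0 give positive rate
  st2 <- modifyList(state0, list(v = -40, Ca = 0))
  expect_gt(calcium_derivative(st2, stn), 0)
})

test_that("synaptic gate kinetics follow the sigmoid activation law", {
  syn <- cfg$synapse$gpe_to_stn
  # sigmoid midpoint: v_pre - theta_g = Theta_gH gives H = 1/2
  v_mid <- syn$theta_g + syn$Theta_gH
  for (s in c(0, 0.4, 1)) {
    expect_equal(synaptic_gate_derivative(s, v_mid, syn),
                 syn$alpha * 0.5 * (1 - s) - syn$beta * s)
  }
  # far below threshold: pure decay -beta s0
  expect_equal(synaptic_gate_derivative(0.6, -200, syn), -syn$beta * 0.6,
               tolerance = 1e-6)
  # saturated gate under full drive decays at -beta
  expect_equal(synaptic_gate_derivative(1, 1000, syn), -syn$beta)
})

test_that("synaptic current sums afferent gates", {
  syn <- cfg$synapse$gpe_to_stn
  expect_equal(synaptic_current(-60, c(0, 0, 0), syn), 0)
  expect_equal(synaptic_current(syn$v_syn, c(0.3, 0.8), syn), 0)
  p <- syn; p$g_syn <- 0.5; p$v_syn <- -85
  expect_equal(synaptic_current(-60, c(0.2, 0.3, 0.5), p), 0.5 * 25 * 1.0)
  expect_equal(0.5 * 25 * 1.0, 12.5)
})

test_that("network RHS handles dimensions, decoupling, and zero conductance", {
  n <- 10L
  top <- network_topology(n)
  st <- random_state(n, seed = 7)
  expect_error(network_rhs(st[-1], 0, cfg, top), "length")

  # all conductances zero, no applied current: dv/dt = 0 everywhere
  dead <- dead_config()
  d <- network_rhs(st, 0, dead, top)
  s <- unpack_network_state(d, n)
  expect_equal(unname(s$stn[, "v"]), rep(0, n))
  expect_equal(unname(s$gpe[, "v"]), rep(0, n))

  # with synapses silenced the network is 20 independent neurons
  un <- uncoupled_config()
  d <- network_rhs(st, 0, un, top)
  su <- unpack_network_state(st, n)
  for (i in c(1L, 6L)) {
    one <- stngpe:::neuron_rhs(su$stn[i, ], un$stn, i_syn = 0, i_ext = 0)
    got <- unpack_network_state(d, n)$stn[i, ]
    expect_equal(unname(got), unname(one), tolerance = 1e-12)
  }
})

test_that("compiled and reference RHS implementations agree", {
  n <- 10L
  top <- network_topology(n)
  for (seed in 1:5) {
    st <- random_state(n, seed)
    for (iext in c(0, 5)) {
      inp <- if (iext == 0) input_spec("none") else input_spec("sine", A = 5, omega0 = 1000 / 4)
      # quarter-period of a sine with period 4 ms at t = 1 gives exactly A
      d_r <- network_rhs(st, 1, cfg, top, inp)
      d_c <- stngpe:::network_rhs_cpp(st, n, stngpe:::pack_cell(cfg$stn),
                                      stngpe:::pack_cell(cfg$gpe),
                                      stngpe:::pack_syn(cfg$synapse$stn_to_gpe),
                                      stngpe:::pack_syn(cfg$synapse$gpe_to_stn),
                                      iext)
      expect_equal(unname(d_r), as.numeric(d_c), tolerance = 1e-10)
    }
  }
})

test_that("compiled integration matches the deSolve oracle on a short run", {
  skip_if_not_installed("deSolve")
  n <- 10L
  top <- network_topology(n)
  y0 <- stngpe:::with_preserved_seed(3L, stngpe:::initial_state(cfg, n))
  dt <- 0.05; t_end <- 20
  ref <- deSolve::rk4(y0, seq(0, t_end, by = dt),
                      function(t, y, parms) list(network_rhs(y, t, cfg, top)),
                      parms = NULL)
  got <- stngpe:::rk4_integrate_cpp(y0, n, stngpe:::pack_cell(cfg$stn),
                                    stngpe:::pack_cell(cfg$gpe),
                                    stngpe:::pack_syn(cfg$synapse$stn_to_gpe),
                                    stngpe:::pack_syn(cfg$synapse$gpe_to_stn),
                                    dt, as.integer(t_end / dt), 1L, 0L, 0, 0,
                                    numeric(0), numeric(0), 0)
  expect_equal(as.numeric(got$state_final),
               as.numeric(ref[nrow(ref), -1]), tolerance = 1e-8)
})
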