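---
title: "Beta-band entrainment of a subthalamo-pallidal network model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-band entrainment of a subthalamo-pallidal network model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Hypokinetic symptoms of Parkinson's disease correlate with excessive
synchronized oscillations in the beta band (10–30 Hz here) across cortex and
basal ganglia. Whether these oscillations originate in cortex, striatum, or
in the reciprocally coupled loop between the subthalamic nucleus (STN,
excitatory) and the external globus pallidus (GPe, inhibitory) is debated.
`stngpe` implements a conductance-based STN–GPe network and asks a
resonator's question: when a beta-band current — a stand-in for cortical
drive — is injected into STN, at which frequencies and amplitudes does the
network entrain into strongly synchronized activity?

## The model

The network is two chains of 10 neurons each on a ring: STN neuron *i*
excites GPe neuron *i*; GPe neuron *i* inhibits STN neurons *i−1*, *i*,
*i+1* (indices modulo 10). Each neuron is a five-variable
conductance-based model (`v`, gating variables `n`, `h`, `r`, and
intracellular calcium):

$$C \dot v = -I_{Na} - I_K - I_L - I_{Ca} - I_T - I_{AHP} + I_{app}
             - I_{syn} + I_{STN}(t)$$

with spike currents $I_{Na} = g_{Na} m_\infty^3 h (v - v_{Na})$ and
$I_K = g_K n^4 (v - v_K)$, leak $I_L$, a high-threshold calcium current
$I_{Ca} = g_{Ca} s_\infty^2 (v - v_{Ca})$, a low-threshold T-type current
$I_T = g_T a_\infty^3 b_\infty^2(r) (v - v_{Ca})$ whose inactivation is
carried by the slow variable `r`, and a calcium-activated,
voltage-independent potassium current
$I_{AHP} = g_{AHP} \frac{[Ca]}{[Ca]+k_1}(v - v_{AHP})$. Because $I_{AHP}$
is a potassium current, its reversal `v_AHP` defaults to $v_K = -80$ mV.
Gating follows $\dot x = \phi_x (x_\infty(v) - x)/\tau_x(v)$ and calcium
$\dot{[Ca]} = \epsilon(-I_{Ca} - I_T - k_{Ca}[Ca])$. Synapses are
first-order kinetic gates
$\dot s = \alpha H_\infty(v_{pre} - \theta_g)(1-s) - \beta s$ with
$I_{syn} = g_{syn}(v - v_{syn})\sum_j s_j$. The external current
$I_{STN}(t)$ enters STN neurons only.

The two study parameters are `g_syn`, the GPe→STN (pallido-subthalamic)
conductance, and `I_app`, the constant current to GPe neurons summarizing
striato-pallidal input. Dopamine depletion maps onto larger `g_syn` and
smaller `I_app`; the five shipped presets are
(0.5, 5), (0.5, 7), (0.5, 9), (0.7, 5), (0.9, 5).

Structurally the STN and GPe cells are the same model with different
constants; the one structural switch is the T-current inactivation
(`t_gate`): a sigmoid of `r` squared for STN, `r` itself for GPe, following
the canonical model family this network descends from.

## Where the constants come from

Every constant lives in `inst/extdata/default_parameters.yaml`; nothing is
hard-coded. The cell and synapse values are the canonical Terman-type
subthalamo-pallidal set. That family leaves a handful of operating-point
constants open (bias currents, synaptic rate constants, exact gating
timescales), so these were fixed once, by simulation, to place the five
presets in their intended dynamical regimes, and then frozen:

* **GPe leak** (`g_L` = 1, `v_L` = −63 mV): puts the GPe rheobase just above
  `I_app` = 5, so in the Parkinsonian presets GPe cells fire only when driven
  by STN (the half-center mechanism), while at `I_app` = 7–9 they fire
  tonically on their own and decorrelate the network. Checked from both
  resting and depolarized initial conditions so the operating point is not
  bistable.
* **GPe calcium/AHP** (`k1` = 10, `epsilon` = 5e-4): gives spike-frequency
  adaptation and a graded f–I curve, preventing runaway tonic firing.
* **GPe→STN kinetics** (`alpha` = 3, `beta` = 0.07 ms⁻¹): the ~14 ms decay
  of pallidal inhibition, together with the T-current recovery
  (`tau_r`, `phi_r`), sets the half-center period; the autonomous rhythm of
  the strongly coupled presets sits in upper beta (≈20–24 Hz).
* **STN rebound and bias** (`g_T` = 1.5, `I_app` = 19.8): strong enough
  rebound bursts to sustain the loop, a bias high enough that STN stays
  active under the tonic inhibition of the healthy presets.

The calibration criteria were only the qualitative regime statements
(beta-band bursting with few spikes per burst; synchrony increasing with
`g_syn` and decreasing with `I_app`; the (0.9, 5) preset at or below five
principal components without input). Quantitative acceptance numbers were
computed only after the file was frozen.

## External inputs

Three generators, all bounded by the amplitude `A`:

* `sine`: $A\sin(2\pi\omega_0 t/1000)$, `t` in ms, `omega0` in Hz.
* `noisy_sine`: the same with an i.i.d. Gaussian phase jitter of variance
  0.08 rad² inside the argument, drawn once per integrator step (the
  variance is per draw, not per unit time — this keeps the spectral peak at
  `omega0` while broadening it).
* `phase_derived`: $A\sin(\varphi(t))$ where $\varphi$ is the beta-band
  Hilbert phase of a supplied signal. Patient EEG recordings of the kind
  this mode is meant for are not distributable; `synthetic_cortical_signal()`
  emulates their gross spectral profile (broadband, smoothed-periodogram peak
  near 13 Hz, appreciable 10–30 Hz content) with resonator-shaped Gaussian
  noise plus a white floor, normalized to unit variance. The surrogate
  reproduces none of the nonstationarity, artifacts, or cross-frequency
  structure of a real EEG, so phase-derived results show robustness of the
  entrainment mechanism to broadband phase input, not a reconstruction of
  the patient experiment.

## Analysis chain

* **Surrogate LFP**: the inhibitory GPe→STN current delivered to a site
  neuron and its two ring neighbours, averaged (weights are a parameter of
  `compute_lfp()`).
* **Spiking signal**: binary spike trains from upward crossings of −20 mV
  with a 2 ms refractory period.
* Both are mean-removed, band-passed at 10–30 Hz with a zero-phase
  (forward–backward) Butterworth filter of order 4 — the order is chosen so
  the two-pass response keeps unit passband gain and ≥20 dB attenuation
  5 Hz outside the band — and their instantaneous phases extracted via the
  FFT analytic signal.
* **First-return map**: at every upward crossing of the LFP phase through a
  checkpoint (linearly interpolated in time), the spike phase is recorded;
  consecutive pairs $(\varphi_i, \varphi_{i+1})$ are points on the torus.
  The locked state is the circular mean of the recorded phases; the map is
  partitioned into the four quadrants around it (the synchronization region,
  leaving, desynchronized, returning), and each region's **transition rate**
  is the fraction of its points whose successor lies elsewhere. The final
  map point, having no successor, cannot leave but still counts as
  occupancy; occupancies therefore sum to the number of map points.
* **Experiment matching**: model rates within `k` = 0.7 reference standard
  deviations of reference rates in all four regions (boundary inclusive).
  The reference rates come from patient recordings that are not
  distributable; the shipped values are documented placeholders, so the
  match flag calibrates against whatever reference the user supplies rather
  than reproducing the published comparison.
* **Network synchrony**: the number of principal components of the ten STN
  slow-variable traces (covariance PCA on mean-centred columns) needed to
  capture 80% of variance; 1–3 components = red (most synchronous), 4–5
  green, 6–7 blue, 8–10 black. The identity of "the slow variable" is
  configurable (`r`, `Ca`, or `s`); the default is `r` because it is the
  slowest per-spike state variable and, empirically, the only one of the
  three whose count separates the synchronous from the asynchronous presets
  (calcium is so slow that one component always dominates, and the synaptic
  gates are too fast).

## Sweeps and resonance

`run_sweep()` simulates one cell per (amplitude, frequency) pair, analyses
it, and aggregates over replicate seeds (median component count, majority
match). `minimal_amplitude()` reads off, per frequency, the smallest
amplitude reaching a target count (3 = red, 5 = green);
`tongue_tip()` returns the frequency minimizing that curve — the tip of the
entrainment (Arnold) tongue. Ties are broken toward the deeper local
neighbourhood, then toward lower frequency; for broad, noisy resonance
regions `tongue_tip(smooth = TRUE)` takes the argmin of the
neighbourhood-averaged curve instead, which ignores isolated single-cell
dips.

Study-scale grids are 10–30 Hz × amplitudes 0–16 with ~20 s of analysed
time per cell. The package's reduced protocol — used by the test suite and
`scripts/acceptance.R` — runs 14–24 Hz × amplitudes 0–10, 6 s per cell
(1 s transient discarded), 3 replicate seeds. At this window length the
component count of a single cell fluctuates by ±1–2 across seeds (the
network is chaotic and intermittently synchronous, which is the phenomenon
of interest); the replicate median and the tongue-level aggregation absorb
most of it. Amplitudes above the first one reaching the target can be
skipped (`early_stop_count`) without changing any minimal-amplitude curve.

## Numerical choices

* Fixed-step RK4 (compiled) with `dt` = 0.05 ms, traces recorded every
  0.25 ms (4 kHz). Spike counts of regular (uncoupled) dynamics change by
  under 1% when `dt` is halved. Trajectories of the coupled network are
  chaotic, so individual runs are not reproduced across `dt`; regime
  statistics were established at `dt` = 0.05 ms and the step is part of the
  configuration.
* Initial conditions: `v` uniform on [−65, −55] mV per neuron, gating
  variables at their steady state for the drawn `v`, `[Ca]` = 0.3, gates
  `s` = 0; all drawn from the run seed. Randomized initial conditions avoid
  ring-symmetric artifacts.
* Every random draw (initial conditions, input jitter, surrogate noise) goes
  through one seeded stream; a simulation is bit-reproducible from
  `(config, input, seed)`, and sweep cells derive their seeds from the base
  seed and cell index so interrupted sweeps resume identically.
* Degenerate cases: a perfectly uniform return map (undefined circular mean)
  falls back to the densest-quartile centre with a message; empty map
  regions report `NA` rates and make the experiment match false with a
  recorded reason; zero-variance PCA input errors.

## Known limitations

* The network is 20 neurons on a ring; there is no thalamo-cortical feedback
  loop, no striatal or cortical population, and no parameter heterogeneity
  beyond the configuration file.
* The default parameter file realizes the intended qualitative regimes of
  the presets, but it is a reconstruction: the precursor model's exact
  constants were not available, so quantitative statements transfer only at
  the level the reduced protocol checks (resonance location bands, the
  zero-amplitude floor, input statistics).
* The experiment-match criterion is fully implemented but only as calibrated
  machinery: its reference rates are user configuration, not shipped
  measurements.
* Component counts from 5 s windows are noisy by nature; single-cell colours
  in reduced-scale sweep maps should be read through the replicate
  aggregation, not individually.
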