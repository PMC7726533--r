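# ispneuron

Inhibitory synaptic plasticity and flexible receptive-field switching in a
single conductance-based neuron.

## The scientific problem

Cortical neurons receive tuned excitation together with inhibition from
several interneuron populations. When inhibition precisely balances
excitation stimulus-by-stimulus ("detailed balance"), the neuron's mean
response is indiscriminate — the receptive field is latent. Modulating the
firing rate of one inhibitory population (disinhibition) can then unmask
it. This package simulates the minimal model of that idea: one
leaky integrate-and-fire (LIF) neuron, a tuned excitatory afferent
population organised in *signal groups* (stimulus features), and one or two
inhibitory populations whose weights are learned by biologically motivated
plasticity rules. It is aimed at computational neuroscientists who want a
small, fully reproducible sandbox for inhibitory-plasticity and
gain-modulation questions.

## Model

Membrane potential (voltages in mV, times in ms, conductances in leak
units):

    tau_m du/dt = -(u - u_rest) - g_E (u - E_E) - g_I (u - E_I)

with exponentially decaying conductances `tau_X dg_X/dt = -g_X` that jump
by the synaptic weight `w_j` at each presynaptic spike. Spikes are
threshold crossings at `u_th`, followed by a reset to `u_reset` and a 5 ms
clamp.

Natural input: each signal group carries a latent Ornstein–Uhlenbeck
variable `y_mu` (updated every 1 ms, zero mean); afferents of population X
in group mu fire as an inhomogeneous, refractory-corrected Poisson process
with rate `nu_X0 [y_mu]_+ + nu_Xbg` (Hz), shared within the group. Pulse
input steps one group to `alpha_X k nu*` for 100 ms.

Inhibitory plasticity rules (presynaptic/postsynaptic spike traces `x` with
`tau_STDP = 20 ms`):

* **Hebbian** — `dw/dt = eta_H [x_j S_post + x_post S_j - alpha_H S_j]`:
  coincidence potentiates, lone presynaptic spikes depress. Stable rate
  setpoint `rho_0 = alpha_H / (2 tau_STDP)` = 5 Hz; learns a *co-tuned*
  inhibitory profile.
* **Scaling** — homeostatic: additive potentiation of all synapses when a
  slow rate estimate exceeds `alpha_s rho_0`, multiplicative depression
  below `rho_0/alpha_s`; learns a *flat* profile and forgets initial
  conditions.
* **Anti-Hebbian** — the sign-flipped Hebbian rule (unstable on its own),
  run with an exponentially decaying learning rate; learns a
  *counter-tuned* profile.

Responses are quantified by per-group Pearson correlations `C_mu` between
the low-pass-filtered group input and the filtered output, the performance
index `delta_C = (C_pref - C_nonpref)/2`, CV of interspike intervals, rate
statistics, and phasic/tonic (first/last 50 ms) pulse responses.

## Worked example

A quarter-scale model (800 excitatory / 200 inhibitory afferents in 8
signal groups), two minutes of Hebbian learning, then a frozen-weight
probe:

```r
library(ispneuron)

hebbian_fixed_point(alpha_H = 0.2, tau_STDP = 20)
#> Mean-field hebbian rule: fixed point 5 Hz (stable)

model <- isp_model("hebbian", scale = 0.25, seed = 1)
fit   <- train_inhibition(model, duration = 120e3, seed = 2)
summary(fit)
#> Training summary (2.0 min): final rate 13.16 Hz
#> per-group mean weight profiles:
#>               [,1]  [,2]  [,3]  [,4] [,5]  [,6]  [,7] [,8]
#> excitatory   0.247 0.280 0.359 0.600 1.00 0.601 0.360 0.28
#> inhibitory_1 0.930 1.042 1.053 1.221 1.87 1.352 1.006 0.92

probe(fit, duration = 60e3, seed = 3)
#> Session: 60.0 s natural input, gains (1)
#>   output: 336 spikes, 5.60 Hz (SD 3.20 Hz), CV_ISI 1.28
#>   performance index delta_C = 0.111 (C_pref 0.164, C_nonpref -0.059)
```

The training-session rate (13.2 Hz) averages over the initial transient;
the subsequent probe shows the learned state: the inhibitory profile now
mirrors the excitatory tuning (peak at the preferred group 5), the output
rate sits near the 5 Hz setpoint, spiking is irregular (CV above 1), and
the response is weakly correlated with any single group (`delta_C` near
0). Switching experiments then follow with `compensatory_gain()` /
`probe(..., gains = c(0, g))` (deactivate one population, restore the mean
rate with the other) and `pulse_sweep()` for transient responses; see
`?gain_sweep`, `?reproduce_protocol` and the vignette.

A thin command-line front end with `train`, `probe`, `pulse`,
`compensate`, and `reproduce` subcommands is installed at
`inst/cli/ispneuron.R`.

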