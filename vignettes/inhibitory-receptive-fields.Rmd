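---
title: "Methods: inhibitory plasticity and receptive-field switching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inhibitory plasticity and receptive-field switching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ispneuron)
```

This vignette is the package's own account of the model it implements: the
equations, the assumptions behind them, the tunable parameters, the
numerical conventions the simulator fixes where the mathematics is
ambiguous, and the known limitations of desk-scale runs.

## The model

A single postsynaptic conductance-based LIF neuron receives $N_E$ tuned
excitatory afferents and $N_I$ inhibitory afferents split into one or two
populations. Membrane dynamics:

$$\tau_m \frac{du}{dt} = -(u - u_\mathrm{rest}) - g_E (u - E_E) - g_I (u - E_I),$$

with dimensionless conductances (leak units) that decay exponentially
($\tau_E = 5$ ms, $\tau_I = 10$ ms) and jump by the synaptic weight $w_j$
at each presynaptic spike. A threshold crossing at $u_\mathrm{th} = -50$
mV emits a spike; the voltage is reset to $-65$ mV and clamped for the
$\tau_\mathrm{ref} = 5$ ms refractory period (conductances keep evolving).
All times are in ms, voltages in mV, rates in Hz; the integration step is
$\Delta t = 0.1$ ms.

Afferents are organised in $P$ signal groups that stand in for stimulus
features. Excitatory weights are fixed and follow the bell-shaped profile

$$r(\mu) = \frac{1}{1+r_0} + \frac{r_0}{1+r_0}\,\frac{1}{1 + b(\mu-\mu_0)^c},$$

with $r_0 = 4$, $b = 0.25$, $c = 2$ and preferred group $\mu_0 = 9$ of 16
at full scale; $w_j = w_{E0}\, r(\zeta_j) + \epsilon_j$ with uniform noise.
Inhibitory weights start flat with noise and are plastic.

### Natural and pulse input

Each group carries a latent variable $y_\mu$ updated on a 1 ms grid,
$y \leftarrow y + \Delta T(-y/\tau_{OU}) + \xi$, $\xi \sim
\mathcal N(0,1)$ per update. Afferents of population $X$ in group $\mu$
fire as a Bernoulli process with per-step probability $\nu\,\Delta t$,
$\nu = \nu_{X0}[y_\mu]_+ + \nu_{X\mathrm{bg}}$, suppressed for a
per-population refractory period (5 ms excitatory, 2.5 ms inhibitory), so
the realised afferent rate is
$F = (p/\Delta t)(1-p)^{\tau_\mathrm{ref}/\Delta t}$. Pulse input holds
all groups at background and steps one group to
$\alpha_X k \nu^* + \nu_{X\mathrm{bg}}$ for 100 ms.

**Noise scaling of the OU update.** The update adds a unit-SD Gaussian
per 1 ms step rather than a $\sqrt{\Delta T}$-scaled one. This gives a
stationary SD of $\sqrt{\tau_{OU}/2\Delta T} = 5$, and hence
active-period rates of tens of Hz; the continuous-time scaling would make
the modulation negligible against the background rate and destroy the
long-tailed ISI statistics the generator is meant to emulate. The
rectification makes each group "active" half the time.

### Plasticity rules

Spike traces $x$ (decay $\tau_\mathrm{STDP} = 20$ ms, $+1$ per spike) are
kept for every inhibitory afferent and for the postsynaptic neuron.

* **Hebbian**: at a presynaptic spike,
  $w \leftarrow [w + \eta_H (x_\mathrm{post} - \alpha_H)]_+$; at a
  postsynaptic spike, $w \leftarrow w + \eta_H x_j$. The depression bias
  creates a stable rate setpoint
  $\rho_0 = \alpha_H / (2\tau_\mathrm{STDP}) = 5$ Hz
  (`hebbian_fixed_point()`).
* **Scaling**: a leaky estimator $y_\mathrm{post}$
  ($\tau_\mathrm{scaling} = 1$ s, jump $1/\tau_\mathrm{scaling}$, hence
  units of Hz) drives additive potentiation
  ($+\eta_s w_{Is}(y_\mathrm{post}-\rho_0)$) above $\alpha_s\rho_0$ and
  multiplicative depression ($-\eta_s w (\rho_0 - y_\mathrm{post})$)
  below $\rho_0/\alpha_s$, with a dead zone in between. Multiplicative
  down / additive up makes all weights converge toward a common value
  independent of the start (`scaling_limit_weight()` evaluates the exact
  alternating-schedule solution).
* **Anti-Hebbian**: the sign-flipped Hebbian rule with threshold
  $\rho_1 = \alpha_{aH}/(2\tau_\mathrm{STDP}) = 4.125$ Hz. It is unstable
  (rates run away from $\rho_1$), so its learning rate decays as
  $\eta_{aH}(t) = \eta^*_{aH} e^{-(t-t_0)/\tau_{aH}}$, freezing the
  learned counter-tuned profile.

**Unit convention for $\eta_s$.** The printed value $\eta_s = 10^{-7}$ is
interpreted as a *per-integration-step* rate on the canonical 0.1 ms grid
(like the per-event rates of the spike-triggered rules); a step of length
$dt$ applies the increment scaled by $dt/0.1\,\mathrm{ms}$. Under a
per-ms reading the cumulative multiplicative-depression factor over a
30 min session is bounded by
$\exp(\eta_s \rho_0 T) = \exp(0.9) \approx 2.5$ even for a permanently
silent neuron, which cannot produce the collapse of an initially
dispersed weight population that the rule exists for; the per-step
reading is the weakest convention that can. Even so, collapse strength
is limited by how rarely the 1 s rate estimate leaves the
$[\rho_0/\alpha_s,\ \alpha_s\rho_0]$ dead zone (see Limitations).

### Numerical conventions

The continuous equations leave several discrete choices open; the
simulator fixes them so results are exactly reproducible, and the pure-R
reference implementations in the test suite pin the C++ kernel to the same
scheme:

* Per step: decay conductances (Euler factor $1 - \Delta t/\tau$), add
  spike increments, Euler-update the voltage with the new conductances,
  test the threshold. Spikes are registered at step boundaries; no
  sub-step interpolation.
* Traces decay by the exact factor $e^{-\Delta t/\tau}$ (eliminating
  discretisation drift against the closed-form oracle); weight updates at
  a spike read trace values *before* that spike's own $+1$ increment;
  simultaneous pre/post events apply their updates independently in
  afferent-index order.
* Weights are floored at 0 everywhere; no upper bound.
* The scaling estimator starts at $\rho_0$ (starting at 0 would fabricate
  a depression episode while the estimator warms up); traces start at 0.
* Input generation draws geometric skip lengths within each 1 ms block of
  constant rate — mathematically identical to per-step Bernoulli draws,
  which the tests verify against the analytic rate formula.
* All randomness flows through R's RNG: a session is bit-identical given
  its seed, and run manifests record every seed.

### Correlation metrics

Group input series $Z_\mu$ pool the *excitatory* spikes of group $\mu$
through a $\tau_Z = 10$ ms leaky filter; the output series $Y$ filters the
postsynaptic train with $\tau_Y = 250$ ms. $C_\mu$ is the Pearson
correlation over the session on the $\Delta t$ grid, after discarding a
5 s transient (the slow filter needs $\approx 20\tau_Y$ to equilibrate;
sessions shorter than four transients skip the discard). The performance
index is $\Delta C = (C_\mathrm{pref} - C_\mathrm{nonpref})/2$. Pulse
responses subtract matched background-only trials and convert 50 ms
window counts to Hz ($\times 20$); "signals recovered" counts groups
strictly above half the maximum phasic response.

## Experiments

`train_inhibition()` runs the closed loop for 30 simulated minutes (times
the model scale). `probe()` freezes plasticity. `gain_sweep()` scales an
inhibitory population's rate (gain 1 = control, 0 = inactive — silencing
is a rate-level, not weight-level, operation). `compensatory_gain()`
bisects the active population's gain until the mean output rate matches
the 5 Hz target within ±0.1 Hz on a probe (output rate decreases
monotonically with inhibitory gain, which is checked on the bracket).
Probe seeds are kept disjoint from training seeds.

## Desk-scale runs

`isp_model(scale = s)` shrinks the model so the full workflow runs on a
laptop: the group count and every per-group afferent count scale by
$\sqrt s$ (total afferents by $s$), training time by $s$. Three quantities
must be mapped, not merely shrunk, to keep the scaled model a faithful
miniature:

* the fixed excitatory baseline $w_{E0}$ scales by the inverse per-group
  count ratio, preserving total excitatory drive;
* the preferred group maps proportionally (9/16 → 5/8 at $s = 0.25$);
* the tuning slope scales as $b\,(P_\mathrm{full}/P_s)^c$, preserving the
  profile shape over the normalised group axis — without this the scaled
  receptive field is flatter (endpoint contrast 0.36 instead of 0.247)
  and the counter-tuning signature of flat-population deactivation
  drowns in probe noise.

Initial inhibitory baselines are left at their nominal values: they are
plastic and converge to wherever balance requires.

The test suite runs at $s = 0.25$ (800 excitatory / 200–400 inhibitory
afferents) with 5–7.5 min sessions and 5 min probes, except the
mean-field-agreement check, which uses the full-scale model for 5 min.

## What the generator emulates — and what it does not

The synthetic input reproduces: within-group shared rate fluctuations with
$\approx 50$ ms autocorrelation, independent groups, refractory-corrected
Poisson spiking, long-tailed ISIs (afferent CV above 1), and background
versus active states of equal long-run occupancy. It does **not** emulate
cross-group stimulus correlations, oscillations, adaptation, or any
naturalistic stimulus front-end; passing tests therefore demonstrate the
plasticity and modulation logic under the stated input statistics, not
performance on real sensory streams.

## Known limitations

* The mean-field setpoint neglects pre/post spike correlations.
  Inhibitory afferents are anticorrelated with the postsynaptic spike
  train (their spikes transiently hyperpolarise it), which weakens
  Hebbian potentiation and settles the closed loop slightly *above*
  $\rho_0$; the offset grows as individual weights grow, i.e. as the
  model shrinks. The full-scale loop sits within a few percent of 5 Hz;
  the quarter-scale loop about 20% above.
* Scaling-rule collapse toward a single weight value is directionally
  robust (and the learned mean forgets the initial weights to well under
  1%), but its *magnitude* over one session is modest: with the printed
  learning rate the 1 s rate estimate rarely leaves the dead zone once
  the Hebbian partner holds the rate near target, so the dispersion
  shrinks only a few-fold rather than collapsing outright.
* Anti-Hebbian outcomes are sensitive to initial conditions and to the
  learning-rate decay time, as expected for an unstable rule stabilised
  only by annealing; with the default initialisation the counter-tuned
  population ends near-silent at its tuning trough.
* Single neuron only: no recurrence, no dendrites, no adaptive threshold,
  no short-term plasticity; excitatory synapses are fixed by assumption.
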