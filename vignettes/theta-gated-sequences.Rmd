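---
title: "Theta-gated sequence transmission in an MEC microcircuit model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Theta-gated sequence transmission in an MEC microcircuit model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetagate)
```

## Scientific problem

Layer II of the medial entorhinal cortex (MEC) contains excitatory stellate
cells that are not directly coupled to each other: they interact only through
a dense mesh of fast-spiking inhibitory interneurons. Stellate cells carry a
hyperpolarization-activated cation current (h-current) and a persistent
sodium current, which together produce subthreshold membrane oscillations and
*post-inhibitory rebound spikes* — a cell that has just been released from
sustained inhibition fires. In such a purely inhibition-coupled circuit,
activity can propagate as a sequence: an external input recruits one
interneuron group, whose inhibition both silences its competitors
(winner-take-all) and primes the stellate cells it targets to fire on
release.

This package implements a conductance-based model of that circuit and the
question it was built to answer: under what conditions does a spatially
ordered input sequence drive a *reliable* — repeatable across noisy trials —
sequence of stellate responses, and how does a theta-band (6–12 Hz)
oscillatory drive onto the interneurons gate that reliability?

## Model

### Stellate cell

A single compartment with membrane equation (potentials in mV, time in ms,
currents in µA/cm², conductances in mS/cm²)

$$C \dot V = I_{ext} - I_{Na} - I_K - I_L - I_h - I_{NaP} - I_{syn} - I_{noise},$$

with

* $I_{Na} = g_{Na} m^3 h (V - E_{Na})$, fast transient sodium; $m$ and $h$
  follow first-order kinetics $\dot x = \alpha_x(V)(1-x) - \beta_x(V) x$,
* $I_K = g_K n^4 (V - E_K)$, delayed rectifier,
* $I_L = g_L (V - E_L)$, leak,
* $I_{NaP} = g_{NaP}\, m_s (V - E_{Na})$, persistent (non-inactivating)
  sodium with $\dot m_s = (m_{s,\infty}(V) - m_s)/0.15$,
* $I_h = g_h (0.65\, m_{hf} + 0.35\, m_{hs})(V - E_h)$, a two-component
  h-current whose fast and slow gates relax to voltage-dependent steady
  states with voltage-dependent time constants (tens to hundreds of ms).

The rate functions are available from `gating_rates()` and
`gating_kinetics()`; the full derivative is exposed in pure R as
`stellate_derivative()` so every term can be inspected and tested
independently of the compiled integrator. The interplay of $I_h$ and
$I_{NaP}$ gives the cell subthreshold oscillations on the order of a
millivolt at its resting drive and a rebound spike upon release from
inhibition — the two
behaviours the `fig1a` preset characterises.

### Fast-spiking interneuron

A single-compartment fast-spiking model,

$$C \dot V = I_{ext} + I_{pulse} - I_{Na} - I_K - I_L - I_{syn} - I_{noise} - I_\theta,$$

with the gate kinetics of the h (inactivation) and n gates multiplied by a
temperature-like factor $\phi = 5$, which is what allows sustained
high-frequency firing. The fast sodium activation gate is treated as
instantaneous, $m = m_\infty(V)$: with $\phi$ applied to $h$ and $n$ but a
dynamic un-accelerated $m$, the model enters depolarization block and cannot
fire at all, so the source model's instantaneous-$m$ form is used
(`interneuron_derivative()`).

### Synapses

First-order kinetic synapses: each presynaptic cell owns one gating variable

$$\dot s = F(V_{pre})\, \alpha_s (1 - s) - \beta_s s, \qquad
F(V) = \tfrac{1}{2}\bigl(1 + \tanh(V/4)\bigr),$$

shared across all of its targets, and each connection contributes
$I_{syn} = g\, s\, (V_{post} - E_{syn})$ to its target. Excitatory synapses
have $E_{syn} = 0$ mV, $\alpha_s = 100$, $\beta_s = 0.33$; inhibitory
synapses $E_{syn} = -80$ mV, $\alpha_s = 3.33$, $\beta_s = 0.11$ (rates in
ms⁻¹ — the printed constants are only dimensionally consistent with
millisecond-scale synaptic kinetics).

### External drives

* **Theta:** a sinusoidal conductance onto every interneuron,
  $I_\theta = A \sin(2\pi \omega t + \phi_0)(V - V_{th})$ with $A = 0.04$
  mS/cm² and $V_{th} = -80$ mV, entering the interneuron equation with a
  minus sign. The positive half of the sinusoid therefore *hyperpolarizes*:
  phases in $(\pi, 2\pi)$ form the depolarized ("receptive") half-cycle.
  `theta_drive()` also supports a swept instantaneous frequency (sinusoidal
  between `f_min` and `f_max`), with the accumulated phase kept continuous
  (`theta_phase()`).
* **Sequential pulses:** interneuron at position $i$ of the input order
  receives current pulses with onsets $t = t_0 + iT + k\lambda$, rising from
  a baseline $p_{low} = -0.05$ to $p_{high} = 1.0$ µA/cm² with
  $\tau_r = 1$ ms, holding for 40 ms and decaying with $\tau_f = 2$ ms
  (`pulse_train()`, `pulse_current()`). This emulates a spatially ordered
  input — e.g. a moving animal activating grid-like inputs one after
  another — abstracted as position on a ring. The
  default inter-neuron interval $T = 125$ ms places one pulse per 8 Hz theta
  cycle, and the revisit interval $\lambda = NT$ corresponds to one full
  traversal of the ring.
* **Noise:** a per-cell conductance noise $I = g_{amp} u (V - E_{rev})$ with
  $u \sim U(-1,1)$ redrawn every integration step, $E_{rev} = -65$ mV.
  $g_{amp} = 0.04$ mS/cm² was calibrated so the mean absolute noise current
  at a $-70$ mV holding potential is about 10% of the pulse amplitude
  (the driving force vanishes exactly at $E_{rev}$, so the calibration uses
  a nearby physiological resting level).

### Networks

`build_motif()` is the elementary unit: two mutually inhibitory interneurons,
each inhibiting one stellate cell, each stellate cell exciting the *other*
interneuron. With feedback excitation the motif is an autonomous anti-phase
oscillator; without it, one interneuron wins permanently; at elevated drive
it becomes a bistable switch toggled by a transient pulse.

`build_ring()` scales this up: `n_interneuron` interneurons are all-to-all
inhibitory (winner-take-all), each inhibits the 5 stellate cells centred on
its ring position with a Gaussian weight profile (σ = 1.25 positions,
peak-normalised at $g_{ie} = 0.6$), and each stellate cell excites 6
interneurons drawn uniformly at random under a topology seed with weight
$g_{ei} = 0.03$. `build_asymmetric_ring()` replaces the random feedback with
a local profile centred 2 positions downstream (total weight matched), and
`build_dual_ring()` wires two interneuron populations to one stellate ring
so two input streams compete. Population sizes (40 + 40 by default, 16 + 16
in some presets) are this package's own choice of problem size: large enough
for a clear ring geometry and winner-take-all pool, small enough that a
10-trial, multi-second experiment runs in minutes on one core.

## Numerical choices

The production integrator is fixed-step forward Euler at `dt = 0.01` ms, the
conventional choice for this model class; `simulation_config()` exposes both
the step and a classical fixed-step RK4 (`method = "rk4"`,
`reference_integrate()`) used as a discretization oracle. Gating variables
are clamped to $[0,1]$ after every step and clamp events are counted (they
do not occur in normal operation — this is asserted in the tests). Spikes
are detected online as upward crossings of 0 mV with linear interpolation
and a 2 ms refractory window. Integration diverging past $|V| > 200$ mV is
an error, not a warning.

Reproducibility: every trial derives its initial voltages (uniform in
$[-70, -60]$ mV unless fixed values are supplied; gates at their
steady state) and its noise stream from one integer trial seed via a
dedicated counter-based generator, so results are bitwise reproducible and
independent of R's global RNG state. Network topology uses a separate seed,
so "same circuit, new noise" is the natural default of `run_trials()`.

Forward Euler at 0.01 ms tracks the RK4 reference to within a millisecond
per spike over one second for the stellate cell. For tonically
fast-firing interneurons the O(dt) phase error accumulates over hundreds of
inter-spike intervals, so individual late spike times drift by several
milliseconds even though rates, regimes and attractors are unchanged
(halving the step halves the drift; the RK4 reference is self-convergent to
microseconds). Analyses in this package therefore compare regimes,
phase statistics and SPIKE distances — quantities robust to a uniform phase
drift — rather than individual late-spike timestamps.

## Analyses

* `spike_phase()` / `phase_histogram()`: spike phases relative to the
  accumulated theta phase, with circular mean and resultant length.
* `spike_train_distance()`: the time-resolved SPIKE dissimilarity
  (parameter-free, bounded in $[0,1]$, 0 only for identical trains),
  implemented from its piecewise definition with auxiliary endpoint spikes
  and integrated *exactly* over the analysis interval (the profile is
  piecewise linear between merged-train events). A brute-force grid
  evaluation (`spike_profile_grid()`) is retained purely as an independent
  cross-check.
* `reliability()`: per-neuron mean pairwise SPIKE distance across trials —
  the package's measure of trial-to-trial reliability.
* `rate_map()`: Gaussian-smoothed trial-averaged firing rate, which for a
  ring traversed periodically is the model's analogue of a periodic firing
  field.

## Experiment presets

`list_experiments()` names a preset per published-figure regime, from
single-cell characterisation (`fig1a`) through motif regimes
(`fig1b`–`fig1d`), reliability contrasts (`fig2`, `fig3`, `fig6b`), phase
analyses (`fig4`, `fig4g`, `fig6a`), asymmetric and swept-drive variants
(`fig5`, `fig6c`), dual-ring gating (`fig7`) and the slow 2 Hz regime
(`fig9`). Each returns a tibble of machine-checkable predicates encoding
the qualitative claims of the corresponding regime, and takes a single seed
that scopes all randomness. `inst/scripts/thetagate` wraps these in a
command line (`run`, `list`, `fixtures`).

```{r presets}
list_experiments()
```

## Design rationale for unspecified constants

Constants not fixed by the source models were chosen once, before the test
suite was frozen, with these rationales:

* Stellate membrane capacitance 1.5 µF/cm² and leak ($g_L = 0.5$,
  $E_L = -65$): the source stellate model's values, which set the
  subthreshold oscillation frequency range the circuit relies on.
* Theta phase offset π in the presets: aligns pulse onsets (at multiples of
  $T$) with the start of the depolarized half-cycle, so "pulse in the
  receptive window" is the default condition.
* Motif presets use a single stronger excitatory contact
  ($g_{ei} = 0.15$) than the ring ($0.03$ shared over 6 contacts), so one
  rebound spike suffices to recruit the opposite interneuron — the motif has
  no convergence to sum weak inputs.
* Initial voltages uniform in $[-70, -60]$ mV: below threshold, inside the
  h-current's operating range, wide enough to desynchronise trials.
* Preset analysis windows skip the first two pulse cycles where noted: the
  random initial condition injects a transient that is not part of the
  steady-state claim under test.

## Limitations

* Single-compartment cells; no dendritic or gap-junction coupling.
* The ring is an abstraction of spatial traversal: input order *is*
  position, and speed is encoded only through the pulse interval.
* Forward Euler late-spike drift for fast-firing cells (see above); regime
  and phase-level conclusions are unaffected, individual interneuron spike
  timestamps at second-scale horizons are discretization-limited.
* Strict sample-by-sample monotonicity of circular-mean phase across finely
  spaced drive frequencies sits at the sampling-noise level of a 10-trial
  experiment; the robust quantities are the overall shift and its rank
  ordering.
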