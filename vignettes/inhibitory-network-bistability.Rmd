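---
title: "Synchrony and bistability in inhibitory interneuron networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchrony and bistability in inhibitory interneuron networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ingsim)
```

## The scientific question

GABAergic interneurons become more active, and possibly synchronous,
shortly before seizure onset. `ingsim` implements a network-dynamics
account of that observation: randomly connected, purely inhibitory
networks of spiking interneurons can be *bistable*, with a stable
asynchronous state and a coexisting stable synchronous state, and a brief
perturbation can switch the network from one to the other. Because the
synchronous state also carries a higher population firing rate, a
"bistable transition" simultaneously explains abrupt synchrony and an
abrupt rate increase without any lasting change to the network's inputs.
The package compares two single-cell presets — a healthy control
interneuron and a hyperexcitable interneuron mimicking treatment with
4-Aminopyridine (4-AP), a potassium-channel blocker used as an acute
seizure model — and quantifies how much larger the bistable parameter
regime becomes under hyperexcitability.

## The neuron model

Cells follow a two-variable modified Izhikevich model,

$$C_m \dot V = k(V - v_r)(V - v_t) - u - I_{syn} + I_{app} + I_{perturb},
\qquad \dot u = a\,[\,b (V - v_r) - u\,],$$

with reset $V \leftarrow c$, $u \leftarrow u + d$ whenever
$V \ge v_{peak}$, and a piecewise scaling factor $k = k_{low}$ for
$V \le v_t$, $k = k_{high}$ above. Units are pF, mV, ms, pA and nS
throughout, which makes the system dimensionally closed
(pF·mV/ms = pA) with no hidden conversions.

`make_preset()` provides the two parameter columns. They differ only in
$C_m$ (73 vs 49 pF), $b$ (−0.2 vs −0.4 nS), $d$ (0.75 vs 1.25 pA) and
$k_{low}$ (0.6 vs 0.4 nS/mV); the 4-AP cell consequently has a lower
rheobase (≈27 vs ≈44 pA by bisection), a steeper FI curve, and stronger
spike-frequency adaptation ($f_{final} < f_{initial}$ under constant
drive, computed by `fi_curve()` from the first and last inter-spike
intervals). $b$ and $k_{low}$ carry most of the rheobase shift; $a$ and
$d$ set the amount of adaptation.

## Synapses and network

Synapses are inhibitory and first-order kinetic:
$I_{syn} = g_{syn}\, s\, (V - E_{syn})$ with $E_{syn} = -75$ mV for every
connection. Each presynaptic spike releases a unitary transmitter pulse of
1 ms during which the gate rises toward
$s_\infty = \alpha/(\alpha + \beta)$ with time constant
$\tau_s = 1/(\alpha + \beta)$; afterwards it decays as $e^{-\beta t}$
($\alpha = 3.7037$, $\beta = 0.3333$ ms$^{-1}$). Both phases have exact
closed forms (`gate_update()`), so gating never accumulates integration
error. All outgoing synapses of a cell share one gate — mathematically
identical to per-edge gates but with O(N) instead of O(N²) state. If a
cell re-spikes during its own active pulse, the pulse clock restarts with
the current gate value as the new $s(t_0)$, preserving continuity; the
gate therefore stays in [0, 1] for any spike train.

Networks are directed Erdős–Rényi graphs: each ordered pair of distinct
cells is connected independently with probability `p_conn` (autapses
excluded — a self-synapse would be a strong artificial self-inhibition,
and the standard random-network convention omits them). Heterogeneity
enters only through the tonic drive: each cell receives a fixed current
drawn from Normal($I_\mu$, $\sigma_I^2$), standing in for the aggregate
excitatory input from pyramidal cells that are, before seizure onset,
firing unremarkably. Draws are kept as drawn; clipping rare negative
values would bias the stated distribution.

## Simulation protocol

`simulate()` integrates the network with forward Euler at
$dt = 0.01$ ms for 2,000 ms. Initial voltages are uniform on (−70, 0) mV
(the distribution shape is a modelling choice; uniform is the
minimal-assumption reading of "randomized on that interval") with
$u = 0$. Spikes during the first 100 ms trigger no transmitter pulse, so
startup transients decay without echoing through the synapses; the
suppression acts on the gates, not the raster, so those startup spikes
remain visible. At 1,000 ms a square pulse of 1,000 pA lasting 2 ms is
added uniformly to every cell — the perturbation that probes for a
coexisting synchronous state. Each integration step (1) computes synaptic
currents from the previous step's gates, (2) Euler-updates all neurons
using the pre-step voltage to select $k$, (3) applies resets, recording
spikes at the end-of-step time, and (4) advances the gates with this
step's spikes. The integrator aborts with a named neuron and time if any
$|V|$ exceeds 10³ mV, converting a silent numerical failure into a
diagnostic. Euler at this step size tracks a 20×-finer integration to
within 0.5 ms per spike over hundreds of milliseconds (tested), which is
ample for measures built on 2 ms smoothing kernels.

The gate bookkeeping is incremental: exponential decay is a shared
per-step factor, so the per-cell sums of presynaptic gates are scaled
once and corrected only for the few sources inside their 1 ms pulse, with
an exact rebuild every 20 ms to stop round-off drift. This is what makes
500-cell, 200,000-step simulations run in about a second.

### The background-activity pulse

To show the perturbation need not be an artificial 1,000 pA kick,
`ou_conductance()` generates background excitatory conductance with an
exact-update Ornstein–Uhlenbeck recursion (mean $g_{e0} = 3$ nS,
correlation time $\tau_e = 2$ ms, diffusion $D_e = 2$, step 0.01 ms;
stationary variance $D_e \tau_e / 2 = 2$ nS²).
`conductance_to_current()` converts conductance to current through the
driving force at rest, $|{-60.6} - 0| = 60.6$ mV per nS. Transients in
such traces motivate `make_ou_pulse_protocol()`: the same protocol with a
320 pA / 5 ms square pulse. Only the perturbation is replaced — the tonic
drive stays deterministic — matching the study design this package
follows.

## Measures

**Synchrony.** `synchrony_measure()` convolves each spike train with a
Gaussian kernel, forms the population-average trace, and returns the
ratio of the time-averaged variance of the average trace to the mean
time-averaged variance of the individual traces. Identical trains give
exactly 1; independent trains give values near 0 (the variance of an
average of N independent traces shrinks like 1/N). Numerical choices that
the definition leaves open, each exposed as an argument:

* *Kernel SD*: 2 ms by default — on the order of the synaptic rise time,
  so it resolves gamma-band coincidence without merging adjacent
  population cycles. A robustness test checks the measure moves by less
  than 0.02 when the evaluation grid is refined 5×.
* *Grid*: 0.5 ms uniform steps across the window, kernel truncated at
  ±5 SD; time averages are discrete means over grid points.
* *Silent cells*: a cell with zero trace variance in the window has no
  defined contribution to the denominator; including it as 0 would
  inflate S without bound. Such cells are excluded and counted
  (`excluded` attribute). If the whole window is silent the measure is
  undefined and returned as `NA` with a reason — never silently 0.

**Windows.** Scores from random initial conditions use (500, 1000] ms;
post-perturbation scores use (1500, 2000] ms. Intervals are half-open on
the left so a spike recorded exactly at a boundary belongs to one window
only.

**Bistability.** For a panel of (g_syn × I_mu) cells,
`delta_synchrony()` gives each cell's seed-averaged S difference
(after − before), and `bistability_measure()` sums the differences that
strictly exceed 0.3. The threshold separates genuine state transitions
from mere "tightening" of already-synchronous firing; summing the
differences themselves (rather than counting threshold crossings) weights
confident transitions more heavily. The threshold is applied to
seed-averaged differences, since the maps it summarizes are themselves
seed averages.

**Rate and classification.** `mean_firing_frequency()` is total spikes /
cells / window length. `classify_synchrony()` labels a network
synchronous when S strictly exceeds 0.25; the boundary value itself is
classified asynchronous (the convention is documented rather than
prescribed by the measure).

**Transition sharpness.** Along a column of increasing $I_\mu$ at fixed
$g_{syn}$, `transition_slope()` finds the first point whose S exceeds
half the *panel-wide* maximum and reports the slope of the segment to the
previous point. Slope magnitudes scale inversely with the current step of
the grid, so they are comparable only within one grid resolution — which
is why the package asserts orderings and crossing-band widths on its own
grids rather than reproducing any particular printed slope table.

## Sweeps

`run_sweep()` simulates each grid cell `n_seeds` times with fresh
topology, drive and initial conditions derived deterministically from a
master seed via a counter-based scheme (cells and replicates get disjoint
seed blocks, so any execution order gives identical results), and stores
every per-replicate score for audit alongside the seed averages.
`compare_panels()`, `slope_table()` and `synchrony_border()` implement
the panel-level summaries. Undefined cells stay `NA` in all outputs.

## The raster fixture generator

`make_raster()` produces rasters with controlled coherence so every
measure is testable without the simulator: a shared periodic train
(`synchronous`, S = 1 by construction), the same train with per-spike
Gaussian jitter (`jittered`; S decreases monotonically with jitter SD),
independent homogeneous Poisson trains (`poisson`, the asynchronous
surrogate), phase-spread synchronous groups (`clustered`, with cluster
phases spaced uniformly over one period), and `silent`. Jitter that
leaves the window is clipped to the window edge, preserving counts.
These fixtures emulate the *statistics* the measures respond to, not
network dynamics: they contain no adaptation, no inhibitory interaction
and no rate heterogeneity, so passing measure tests on fixtures says
nothing about the simulator — which is exercised by its own oracle tests
(fine-timestep single-cell comparison, decoupled-network replay,
perturbation locality, gate closed forms against an adaptive ODE
solver).

## Problem sizes used by the tests

The packaged checks run the full study conditions for single simulations
(N = 500, 2,000 ms, dt = 0.01 ms) and scale down only the breadth of
parameter scans: the zoomed bistability comparison uses a 6 × 8 grid
(g_syn 0.25–1.75 nS, I_mu 140–245 pA in 15 pA steps) with 2 seeds per
cell at the primary condition (p = 0.12, σ = 6 pA) and single-seed 4 × 6
panels over the core of that regime at the robustness conditions
(p ∈ {0.08, 0.16}, σ ∈ {3, 12} pA); the transition-sharpness check sweeps
the g_syn = 1.25 nS slice over I_mu = 200–350 pA with 2 seeds. The zoom bounds were placed, as in the
study this package reimplements, by a coarse reconnaissance of where the
difference map is non-zero. Orderings proved stable well beyond these
sizes in that reconnaissance.

## Known limitations

* No synaptic conduction delays, no gap junctions, no excitatory
  population, and no depolarizing-GABA effects: the model isolates the
  inhibitory-network mechanism and stops before seizure onset itself.
* Heatmap colour maps and per-panel bistability scores depend on grid
  extent and resolution; only orderings and qualitative structure are
  stable across resolutions, and only those are asserted.
* The Euler scheme with end-of-step spike timestamps quantizes spike
  times to dt; measures built on ≥2 ms kernels are insensitive to this.
* Fixture rasters are statistical surrogates, not dynamical ones (above).
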