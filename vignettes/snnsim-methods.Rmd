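---
title: "Compact-model SNN simulation and training: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compact-model SNN simulation and training: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snnsim)
```

## Scope and model framework

`snnsim` targets the prototyping stage of hardware neuromorphic design:
fast, vectorized, time-discrete *compact models* of neurons and synapses,
organized as **groups** — sets of components that share one model and are
advanced together as dense arrays. A network is an unordered collection of
neuron groups (nodes) and synapse groups (edges); all signals between
groups travel as `[batch, time, components]` tensors, with spike signals
restricted to values in {0, 1}.

Every model implements the same three-method lifecycle:

* `time_dep()` precomputes all constants that depend on the time-step size
  `dt` (for example `exp(-dt/tau)`),
* `set_initial_state()` (via `init_state`) builds the default state arrays,
* `advance_timestep()` (via `step`) maps a state and an input slice
  `[B, N_in]` to the next state and an output slice `[B, N_out]`.

All quantities are unitless numbers; the package never attaches physical
units, and the examples follow the common convention of milliseconds for
time constants and `dt`, and millivolts for the Izhikevich voltages. The
user owns unit consistency. State is double precision throughout.

## The component models

**First-order leaky synapse (`ls1`).** Each source/target pair (i, j)
carries a current that decays with `tau_alpha` and jumps by the weight on a
pre-synaptic spike:

$$I_{ij}(t+dt) = I_{ij}(t)\,e^{-dt/\tau_\alpha} + w_{ij}\,\delta_i(t),$$

and the group output towards target j sums all contributions, integrated
over the step:

$$O_j(t) = \varphi \sum_i I_{ij}(t)\,\tau_\alpha\bigl(1 - e^{-dt/\tau_\alpha}\bigr),$$

with `phi` a group-wise scalar. Two consequences of the printed equation
order are deliberate and documented rather than "fixed": the output is
computed from the *pre-update* state, so a spike first influences its
target one step after reaching the synapse; and synaptic groups are always
stored dense (`[n_src, n_tgt]`), with zero weights encoding pruned
connections. Dense storage costs memory but keeps every update a plain
vectorized expression at the scales this package targets (tens of
thousands of synapses per group). A flag removes the temporal integration
factor from the output when plain current summation is wanted.

**Second-order leaky synapse (`ls2`)** solves the double-exponential kernel
by splitting it into two independently decaying branches, `I+` (time
constant `tau_alpha_plus`, incremented by `+w`) and `I-`
(`tau_alpha_minus`, `-w`). On a single impulse the output is exactly the
difference of two first-order kernels — a property the test suite checks
analytically — and with the conventional 15 ms / 5 ms pair it produces the
familiar alpha-like rise and decay.

**Leaky integrate-and-fire (`lif`).**
$u' = u\,e^{-dt/\tau_\beta} + \Pi\,S$; a spike is emitted where
$u' \ge \Theta$ (equality spikes, matching the `O = 0` iff $u < \Theta$
convention), after which the membrane resets to `u_r`. Spike detection
happens after the current step's input is integrated; the reset applies to
the state carried into the next step. Refractoriness gates *only the input
integration*: the gate `Pi` drops to 0 for a duration `rho` after each
spike while the membrane keeps leaking. `rho = 0` means no refractoriness
at all (the gate never closes); this keeps the refractory decorator an
exact no-op at `rho = 0`. The same gating mechanism is available as
`refractory_wrap()` for any spiking model, e.g. Izhikevich.

**Leaky integrator (`li`)** is the LIF with threshold and reset disabled;
its output is the membrane itself. It is the readout layer of choice for
training, because the max-over-time credit assignment needs an analog
trace.

**Izhikevich (`izhikevich`).** Forward-Euler integration of the canonical
two-variable system, `k = ceiling(1/h)` sub-steps per engine step:

$$v \leftarrow v + h\,(0.04v^2 + 5v + 140 - u + S), \qquad
  u \leftarrow (1 - ha)\,u + hab\,v,$$

then spike-and-reset (`v <- c`, `u <- u + d`) where `v >= theta`. The
published rendering of the quadratic term is typographically garbled in
parts of the literature; the canonical `0.04 v^2 + 5 v + 140` polynomial is
what is implemented. `h` (0 < h <= 1) is the stability/accuracy dial; the
suite verifies first-order (O(h)) self-consistency under sub-step
refinement on the standard parameter set `a, b, c, d, Theta =
0.02, 0.2, -65, 8, 30`. The equations carry no `dt`: one engine step is one
unit of model time (1 ms for the canonical constants). Running another
`dt` requires the user to rescale the constants; the engine does not do it
implicitly. Initial conditions are `v = c`, `u = b c`.

## Stack computation

The engine evaluates all groups once per step in a fixed linear order (the
*stack*). The order is scored on the delay-substituted **directed
adjacency matrix** (DAM): for a candidate permutation, entry `[r, c]`
holds the delay of the connection from the group at position r to the
group at position c; non-connections hold `-eps` with
`eps = 1e-9 * dt` — a negative infinitesimal that keeps zero-valued delays
distinguishable from absent connections, and small enough that no sum of
`eps` terms can outweigh a real delay difference at double precision for
any realistic group count. The permutation minimizing the
lower-triangular sum (LTS) wins; ties resolve to the earliest permutation
in lexicographic order over the order groups were added.

Two design points deserve emphasis:

* **Orderings are never rejected.** A connection that lands in the lower
  triangle simply delivers with recurrence semantics (below); if its delay
  rounds to zero steps, it acquires one engine step of implicit latency
  and a warning reports it. Ranking — not rejection — keeps the procedure
  total for every topology, including zero-delay cycles (where the `-eps`
  filler makes the minimum the order with the *fewest* feedback
  connections). The alternative reading, disallowing zero-delay feedback
  placements outright, was considered and dropped: it leaves networks with
  zero-delay cycles (the common case for reservoirs) without any
  admissible order.
* **Enumeration is exhaustive up to 8 groups** (40,320 orders, negligible
  cost) and refuses larger networks unless `heuristic = TRUE` opts into a
  greedy fallback (iterated topological sort, breaking cycles at the
  largest-delay back edge). An explicit flag, not a silent switch, because
  the heuristic does not guarantee the LTS minimum.

For any feedforward network the result is a topological order with no
connection in the lower triangle — the property suite verifies this on
random DAGs, and verifies equality with an independent brute-force
enumeration on hundreds of random small networks.

## Engine, temporary storage, and delays

Simulation is two nested loops: time-steps outside, stack inside. One
storage slot is pre-allocated per group output; each reader's input
address *is* its sources' output slots, so the per-step I/O is index reads
plus one write per group. Slots are short ring buffers over recent steps,
which unifies three mechanisms:

* a feedforward read takes the value written earlier in the same step
  (offset 0);
* a feedback (lower-triangular) read takes the previous step's value
  (offset 1) — the defined recurrence semantics, worth exactly one engine
  step of latency;
* a connection with delay `d` reads at offset `round(d/dt)`, raised to 1
  for feedback reads, so the implicit feedback step realizes the first
  step of the delay and delivery times stay exact whenever
  `round(d/dt) >= 1`. Sub-`dt` delays round to zero with a warning.

External input is injected into the input port's slot before each inner
loop; the output port's slices are collected after it. Slots are
zero-initialized, so the first read of a feedback path sees zeros. By
default the first-added group is the input port and the last-added the
output port; `set_ports()` overrides both.

Monitoring wraps a group's step to record chosen state/output variables
each step, shaped `[B, T, ...]`; it is purely observational (the suite
demands bitwise-identical outputs with and without monitors). A
multi-segment mode re-runs `time_dep` between segments of different `dt`
with state carried over; ring buffers of delayed connections are
re-discretized (and cleared, with a warning) because a buffer indexed in
steps has no exact re-mapping across a `dt` change.

Split-run continuity (`reset = FALSE`) is exact: running T steps equals
running two consecutive halves, bitwise — this is a regression-tested
property, not an approximation.

## Training: surrogate-gradient BPTT

Training is off-line and supervised: selected synaptic weight matrices are
optimized by full (untruncated) backpropagation-through-time; everything
else is frozen. The sequence lengths in the intended tasks are a few
hundred steps, so truncation buys nothing.

The forward pass during training is *identical* to plain inference —
bitwise, a tested property. Only the backward pass substitutes the spike
Heaviside's non-derivative with the normalized fast sigmoid

$$g(u) = \frac{1}{(1 + \beta\,|u - \Theta|)^2},$$

peaking at 1 on the threshold, `beta = 10` by default (configurable; the
source method leaves the constant free, so the default is a package
decision recorded here, not an empirical claim). The spike reset is
treated as constant during the backward sweep (the standard detached-reset
convention), and the refractory gate is not supported on the trainable
path — training expects `rho = 0` there, as in all the intended
architectures.

Credit assignment reads the **peak of the membrane potential** of each
output neuron over the window: `logit[b, j] = max_t u[b, t, j]`, which
requires a non-spiking (LI) output group; the loss is the mean negative
log-likelihood of the softmax. The backward sweep runs time-reversed over
the reversed stack, with analytic adjoints per model (linear recursions
for synapses and LI, surrogate-weighted for LIF) and routes adjoints
across connections at the same offsets the forward pass read from. On
paths free of spiking nonlinearities the gradient is exact; the suite
checks it against central finite differences at `1e-4` relative error.

Two structural optimizations matter in practice:

* **Frozen-prefix caching.** Groups that no trainable weight can influence
  are simulated once per dataset with the plain engine and their output
  traces cached; epochs then re-run only the differentiable tail. For a
  liquid state machine trained on the readout, the reservoir is simulated
  exactly once.
* **ADAM** with the canonical constants (0.9 / 0.999 / 1e-8) and default
  learning rate 1e-3; mini-batches are shuffled per epoch under a seeded
  sub-stream. The source work states no optimizer hyperparameters, so
  these defaults are again package decisions.

## Encoders and synthetic data

* `rate_encode()`: thresholded linear intensity-to-rate conversion (silent
  at or below 20% of the dynamic range, linear up to 500 Hz at full
  intensity by default), realized as per-step Bernoulli draws with
  probability `rate * dt` (Poisson-like; a regular-interval mode exists
  behind a flag — the stochastic choice is a package decision, as the
  conversion is usually stated rate-wise only).
* `spline_upscale()`: cubic-spline temporal upscaling (e.g. 28 raw samples
  to 300 steps); interpolation passes through every original node, with a
  linear fallback below 4 samples.
* `delta_encode()`: change-triggered spike generation in two
  interpretations, both offset-invariant: *bipolar* (UP/DOWN accumulator
  channels, 28 sensors -> 56 channels) and *thermometer* (k graded
  channels per input firing when the per-step change magnitude crosses
  `m * delta`; 4 channels with k = 3 -> 12). The two modes exist because
  published multi-bit delta front-ends are hardware-specific; each mode
  reproduces one of the standard channel-count conventions, and neither
  claims to replicate a particular circuit.

The synthetic generators make every module testable without downloads.
`gen_rate_classes()` emulates rate-coded sensory data: each class drives
its own disjoint channel subset at 100 Hz against a 5 Hz background over a
100-step (1 ms) window — the structure, not the content, of
cochlear-filtered spoken-digit data. `gen_sensor_sweep()` emulates a
linear tactile array swept over embossed patterns: smooth class-dependent
spatial bumps traversed in time, destined for the spline + delta pipeline.
What these generators deliberately *do not* reproduce: within-class
temporal structure, speaker/writer variability, class overlap, channel
correlations of real front-ends. Passing the end-to-end benchmark
therefore demonstrates that the simulator, trainer and analysis chain work
— not that any particular real-data accuracy is attainable.

## Hardware non-ideality analysis

`quantize_weights()` emulates storage on equidistant, symmetric, signed
conductance levels spanning `[-w_max, +w_max]` (range data-derived
per group by default, which makes noiseless quantization
scale-equivariant; a global range is available for hardware realism).
Write noise is Gaussian with `sigma = Delta/6`, placing adjacent level
distributions 6 sigma apart so they cross at 3 sigma — the total
neighbor-overlap probability is `2 * pnorm(-3)`, about 0.27%, i.e. the
conventional "0.3%" figure. Note one consequence the sweeps make visible:
with an even level count, zero is *not* representable, so sparse weight
matrices degrade sharply at low bit widths — the mechanism behind the
rapid accuracy collapse below ~4 bits.

`drift_weights()` applies a parameterized power-law retention model,
$|w|(t) = |w|(t_0)\,(t/t_0)^{-\nu}$, with per-weight exponents drawn from
a Normal(`nu_mean`, `nu_sd`) truncated at zero (signs preserved,
magnitudes never grow). This is an explicitly generic stand-in for
device-calibrated drift compact models: the defaults
(`nu_mean = 0.1`, `nu_sd = 0.02`) are in the range typical of filamentary
memristive devices, and both parameters are exposed. Drift sweeps start
from unquantized trained weights (write-verify storage assumed).

The sweep harnesses rerun the *full* engine per trial (quantization and
drift touch the reservoir too, so cached prefixes would be stale) and
report mean/min/max over independent write-noise trials per bit width,
and mean/sd over random drift iterations per elapsed time.

## Problem sizes, tolerances, and reproducibility

The test and acceptance workloads use desk-scale instances chosen once:
the synthetic 3-class task uses 20 channels, 80 samples per class, 100
steps at `dt = 1`; the benchmark reservoir uses 20/60/3 layers with
160/600 non-zero wirings (weight magnitude ranges scaled so the reservoir
sits at a healthy 30-50 Hz — the regime where reservoir readouts are
known to train well); training runs 30 epochs at batch 16. The
structural-count checks build the full-size 50/125/10 reference
architecture, whose group sizes (6,250 / 15,625 / 1,250; 200 non-zero
input wires) are exact integers independent of scale.

All randomness flows through named sub-streams derived from one master
seed (`substream_seed()`), so adding a monitor, a group, or a sweep never
perturbs another component's draws, and every dataset, wiring, training
run and noise trial is reproducible from a single integer.

Exactness expectations in the suite are deliberately split: determinism,
observer neutrality, split-run continuity, weight round-trips and
`t = t0` drift are *bitwise*; closed-form values (decay factors, kernel
sums, fixed points) are checked to 1e-9–1e-12; statistical checks
(Bernoulli counts, overlap rates, truncated-normal moments) use 3–4 sigma
bands; the end-to-end benchmark is a majority-of-seeds criterion
(>= 90% test accuracy on at least 4 of 5 fixed seeds).

## Known limitations

* Clock-driven only: no event-driven or variable-step integration, by
  design.
* No physical-unit checking; no on-line plasticity rules (the model
  registry accepts user models, which is the intended extension point).
* The trainer covers relay/LIF/LI/ls1/ls2 paths without refractoriness or
  explicit delays on the trainable subgraph; Izhikevich groups can be
  simulated but not trained through.
* Exhaustive stack ordering stops at 8 groups; the greedy fallback is not
  guaranteed optimal.
* Array I/O is plain text (CSV for rasters, traces and weights, YAML for
  network configs); no binary container formats.
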