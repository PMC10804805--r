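# snnsim

Clock-driven simulation and training of compact-model spiking neural
networks (SNNs), aimed at people prototyping *hardware* neuromorphic
systems: you want fast, vectorized, time-discrete models of neurons and
synaptic circuits, arbitrary (including recurrent) topologies without
writing a scheduler, gradient-based training of the synaptic weights, and
a way to ask "what happens to my accuracy when these weights live on
4-bit, drifting memristive devices?"

## What is inside

A network is a set of **groups** — components sharing one model — wired by
synaptic groups that name their source and target. Signals move as dense
`[batch, time, components]` arrays. Built-in models:

| model | description |
|---|---|
| `lif` | leaky integrate-and-fire, `u' = u e^(-dt/τβ) + Π·S`, spike and reset at `u ≥ Θ`, optional refractory gating `Π` for a time `ρ` |
| `li` | leaky integrator (no threshold): analog readout layer |
| `izhikevich` | `v ← v + h(0.04v² + 5v + 140 − u + S)`, `u ← (1−ha)u + habv`, forward Euler with `⌈1/h⌉` sub-steps |
| `ls1` | first-order leaky synapse: `I ← I e^(-dt/τα) + w δ`, output `φ Σᵢ I·τα(1−e^(-dt/τα))` |
| `ls2` | second-order (double-exponential) leaky synapse, split into `I⁺`/`I⁻` branches |
| `input` | relay for externally supplied rasters |

The execution order of groups (the *stack*) is computed automatically by
minimizing the lower-triangular sum of a delay-substituted directed
adjacency matrix over candidate permutations, so feedforward and
recurrent networks run through the same engine; feedback connections read
their source's previous-step output. On top of the engine: monitors,
surrogate-gradient backpropagation-through-time (max-membrane readout,
log-likelihood loss, ADAM), spike encoders (thresholded linear rate
coding, cubic-spline upscaling, bipolar/thermometer delta modulation),
synthetic dataset generators, a liquid-state-machine builder, and
post-training weight quantization / conductance-drift sweeps.

## Worked example: build, run, monitor

Three input channels drive one LIF neuron through a 3×1 synapse group.
The membrane time constant is a *generator function*, swept across the 10
parallel batch simulations from 10 ms to 100 ms:

```r
library(snnsim)

net <- new_network() |>
  add_group("input", "in", n = 3) |>
  add_group("lif", "out", n = 1,
    tau_beta = function(b, shape, rng) array(10 * seq_len(b), c(b, shape))) |>
  add_group("ls1", "syn", source = "in", target = "out",
    tau_alpha = 8, w = matrix(c(0.02, 0.03, 0.04), 3, 1)) |>
  set_ports(input = "in", output = "out")

sim <- init_network(net, dt = 1, batch_size = 10, seed = 1)
sim
#> <snn_sim: 3 groups, dt=1, batch=10, 0 step(s) run>
#>   stack: in -> syn -> out

set_monitor(sim, "out", "u")
x <- rate_encode(c(0.3, 0.4, 0.5), n_steps = 200, dt = 1, seed = 7)
input <- array(rep(unclass(x), each = 10), c(10, 200, 3))
y <- run_network(sim, input)
apply(unclass(y), 1, sum)
#>  [1]  7 13 15 16 16 16 17 17 17 17
```

Longer membrane time constants integrate more of the same input raster,
so the output spike count climbs from 7 (τβ = 10 ms) towards 17
(τβ = 100 ms); `get_monitored_results(sim, "out", "u")` returns the ten
membrane traces `[10, 200, 1]` behind those counts.

## Worked example: train a liquid state machine

A 3-class rate-coded synthetic task (each class drives its own channels
at 100 Hz against a 5 Hz background) through a 20/60/3 reservoir network;
only the reservoir-to-output weights are trained, so the reservoir is
simulated once and cached:

```r
ds  <- gen_rate_classes(n_classes = 3, n_channels = 20, n_per_class = 80,
                        n_steps = 100, seed = 42)
sp  <- split_dataset(ds, 0.85, seed = 42)
net <- build_lsm(n_in = 20, n_res = 60, n_out = 3,
                 nnz_in = 160, nnz_res = 600, seed = 1042)
sim <- init_network(net, dt = 1, batch_size = 16, seed = 42)
pm  <- pair_trainer(sim, "syn_out")
fit <- train_snn(pm, sp$train, sp$test, epochs = 10, batch_size = 16, seed = 42)
round(fit$history[c(1, 2, 5, 10), ], 3)
#>    epoch  loss train_acc test_acc
#> 1      1 3.334     0.451    0.583
#> 2      2 1.058     0.696    0.750
#> 5      5 0.034     1.000    1.000
#> 10    10 0.006     1.000    1.000
```

The fitted model separates the three classes perfectly on the held-out
36 samples (`fit$confusion` is diagonal). Robustness of the trained
weights on analog storage:

```r
sweep_quantization(fit, sp$test, bits = c(1, 2, 4, 8), trials = 5)
sweep_drift(fit, sp$test, times = c(1, 10, 100, 1000), iterations = 20)
```

report accuracy statistics per bit width (equidistant signed levels with
3σ-crossing write noise) and per elapsed storage time (power-law
conductance drift).

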