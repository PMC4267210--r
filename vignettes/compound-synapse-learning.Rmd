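---
title: "Compound memristive synapses: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compound memristive synapses: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memstdp)
```

This vignette explains the probabilistic model behind `memstdp`, the
assumptions baked into the simulator, the parameters that matter and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical and design decisions taken where more than one choice was
defensible.

## 1. The synapse model and its plasticity

A compound synapse is `M` bistable stochastic switches in parallel. A switch
contributes conductance weight `omega` when active and 0 when inactive, so
the synaptic weight is `W_ki = omega * m_ki` with `m_ki` the active count:
`M + 1` discrete levels, `log2(M + 1)` bits per weight. Plasticity is event
driven. Every postsynaptic spike triggers, per input channel, either an LTP
event (presynaptic pulse present, `y_i = 1`): each *inactive* switch flips
active independently with probability `pi_up`; or an LTD event (`y_i = 0`):
each *active* switch flips inactive with probability `pi_down`. Switches
never flip toward the state they already occupy, and presynaptic pulses
alone cause no plasticity.

Two consequences shape everything downstream:

* **Stabilizing weight dependence.** The expected change per postsynaptic
  spike is `(M - m) * omega * pi_up` under LTP and `-m * omega * pi_down`
  under LTD; for balanced probabilities this is
  `pi_up * W_max * (y_i - W_ki / W_max)`, a linear restoring force toward
  the spike-triggered input average.
* **Binomial stationarity in the small-probability regime.** Under i.i.d.
  events that are LTP with probability `q`, each switch's activation
  converges to `p* = pi_up q / (pi_up q + pi_down (1 - q))`. The count
  `m` is itself a Markov chain on `{0, ..., M}`; its *exact* stationary law
  (computable from the `(M+1) x (M+1)` transition matrix, and used as the
  oracle in the tests) deviates from `Binomial(M, p*)` by a total-variation
  distance that grows roughly like `1.2 * pi`. At the reference
  `pi = 1e-3` the binomial description is accurate to TV ~ 0.001; at
  `pi ~ 0.1` it is visibly wrong. The package therefore treats the binomial
  law as what it is — the small-`pi` limit — and verifies it by applying
  many i.i.d. events to a large array of independent synapses at
  `pi = 1e-3`, not by running one fast-switching chain.

The same stationarity argument yields the *equilibrium encoding*: with a
systematic imbalance `delta = (pi_up - pi_down)/pi_up`, the weight fraction
encodes the expected input nonlinearly,
`W/W_max = y / (y + (1 - delta)(1 - y))` (`equilibrium_encoding()`), the
identity when `delta = 0`.

## 2. Network, inference and learning

Network neurons integrate the binary pulse traces linearly,
`u_k = b_k + sum_i W_ki y_i`, and compete by softmax lateral inhibition.
Because the instantaneous rates `r_net * exp(u_k - u_inh)` sum to `r_net`
identically, the network is simulated exactly as a thinned Poisson process:
one uniform decides whether a spike lands in the time step (probability
`1 - exp(-r_net dt)`), a second draws the winner from the softmax. This
sidesteps the question of simultaneous spikes within a step (at most one
network spike per `dt` can occur); the construction is exact for the model,
though a simulator allowing multiple spikes per step would differ
microscopically.

The synapse array encodes a Mixture-of-Gaussians generative model:
`mu_ki = m_ki / M`, shared variance `sigma2 = 1 / W_max`, and (by default)
a uniform prior matching the homeostatic targets. Two routes to the
posterior are implemented — direct Bayes normalization of
`prior * likelihood` in log space, and the potential form
`u_hat_k = b_hat_k - A_k + sum_i W_ki y_i` with
`A_k = sigma2/2 * sum_i W_ki^2` — and their agreement to `1e-12` is a test
invariant. Setting `b_k = b_hat_k - A_k` (`posterior_biases()`) makes the
network's softmax response *equal* to the exact posterior; during learning,
homeostasis absorbs the non-local `A_k` terms implicitly. Gaussian density
values include the full normalization constant, so `mog_log_likelihood()`
returns true log densities; the input-only factor cancels in posteriors.

Learning couples two rules. STDP moves `W_ki` along the gradient of the
expected complete-data log-likelihood (M-step); homeostasis
`db_k/dt = eta_b [r_net c_k - s_k(t)]` holds each neuron's long-run spike
share at `c_k` (constrained E-step). `eta_b` defaults to 20 times the
synaptic learning rate `eta_W = pi_up * W_max`, keeping the E-step faster
than the M-step as the derivation requires.

## 3. Parameters and defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| `dt` | 1 | ms | simulation step |
| `tau` | 10 | ms | presynaptic pulse duration |
| `r_net` | 100 | Hz | total network rate |
| `K` | 10 | – | network neurons |
| `M` | 10 | – | switches per synapse |
| `omega` | 0.1 | weight | so `W_max = 1`, `sigma2 = 1` |
| `pi_up`, `pi_down` | 1e-3 | – | slow, gradual memory formation (`eta_W = 1e-3`) |
| `eta_b` | `20 * eta_W` | – | homeostasis faster than STDP |
| `c_k` | `1/K` | – | uniform target activation |
| presentation | 100 | ms | one pattern per slot |
| `init_active_frac` | 0.5 | – | see below |

Random initialization of the switches is unquantified in the reference
protocol; the package initializes each switch active with probability 0.5
(mid-range weights, the symmetric uninformative choice). The prior over
hidden causes defaults to uniform, consistent with uniform homeostatic
targets; non-uniform targets are supported.

## 4. Input encoding and the synthetic generator

Intensities `x in [0,1]` are encoded as Poisson spike trains with per-step
spike probability `1 - (1 - x)^(dt/tau)`; each spike elicits a rectangular
pulse of duration `tau`, overlapping pulses saturating at 1. The window
convention is half-open, `y_i(t) = 1` iff a spike fell in `(t - tau, t]`,
so a lone spike produces exactly `tau/dt` on-steps. This calibration makes
the trace's time average equal the intensity, `<y_i> = x_i` — the property
every downstream stage relies on, and a test invariant. Traces are
continuous across pattern switches: pulses from the previous pattern still
extend into the first `tau` of the next.

The synthetic generator emulates preprocessed digit data with two-level
prototypes: each of `n_classes` patterns sets ~`on_fraction * N` randomly
chosen channels to 0.9 and the rest to 0.05 (the intensity range the digit
preprocessing maps images into). Supports lean toward disjointness so
mixture components are identifiable. Snapshot datasets draw a prototype,
warm the encoder up for `2 * tau` (after which the pulse trace is
stationary) and read the final binary vector; channel marginals then equal
the prototype intensities exactly.

What the generator does *not* emulate: within-class variability (every
presentation of a class uses the same intensity vector; real handwriting
varies), graded intensities (real pixels take intermediate values),
spatial correlation between neighboring channels, and class imbalance.
Passing tests on this task therefore demonstrate that the learning
machinery recovers a well-separated mixture under the encoding's noise
statistics — not performance on real image data, for which the opt-in
IDX pipeline exists.

## 5. Numerical choices

* All softmax/likelihood arithmetic uses max-shifted log-sum-exp;
  underflow-free for hundreds of binary inputs. An all-`-Inf` potential
  vector is rejected rather than propagated as NaN.
* Truncated draws (conductances to `[0, Inf)`, probabilities to `[0, 1]`)
  use rejection sampling — the standard truncated-normal semantics —
  with clipping available as an option and as the fallback after 1000
  rejections.
* Temporal conductance noise redraws a switch's weight only on an actual
  inactive-to-active flip (not on LTP pulses that leave an already-active
  switch untouched).
* Homogeneous arrays update via vectorized binomial counts; heterogeneous
  arrays flip individual switches from per-switch uniforms consumed in a
  fixed (input, switch) order. The two bookkeeping paths agree exactly when
  fed the same per-switch draws (tested by injection).
* One global RNG stream drives everything in a fixed per-step order
  (encoding draws, spike-occurrence draw, winner draw, plasticity draws),
  so any run is bit-reproducible from one seed, and the optimized training
  loop is provably identical to composing the public `encode`/`wta_step`
  primitives (tested).
* Ties in labeling and classification ("most responsive", "spiked most")
  are broken by a seeded uniform choice among the maxima and flagged in the
  output; test presentations with zero network spikes count as
  classification errors (conservative). Evaluation freezes both synaptic
  and intrinsic plasticity so that measuring the model cannot alter it.
* Degenerate inputs: `x = 1` encodes to spike probability exactly 1;
  `pi_up q + pi_down (1 - q) = 0` signals an undefined equilibrium;
  `W_max = 0` is rejected in the hardware-to-theory mapping.

## 6. Measurement conventions

The monitored log-likelihood uses one fixed snapshot dataset (default 5000
samples) drawn once per run, with the Monte-Carlo standard error of the
mean recorded alongside; "non-decreasing" is always judged up to twice the
combined SE of adjacent checkpoints. Homeostatic convergence is measured
from the per-neuron spike counts of the run itself (the quantity the fixed
point concerns); a frozen-excitability replay would instead sample a single
realization of the `b` equilibrium wander and overstate the deviation.

Parameter recovery compares each labeled neuron's `mu_ki = m_ki/M` to its
prototype's intensities (transformed by `equilibrium_encoding()` when
switching is systematically unbalanced). One caveat follows directly from
the theory above: at stationarity `m_ki` *fluctuates* binomially around its
equilibrium, so with `M = 10` the per-channel probability of landing within
±0.1 of the target is at most ~0.93 (on-channels at 0.9) / ~0.91
(off-channels at 0.05). The expected fraction of channels within ±0.1 is
therefore capped near 0.92 no matter how long training runs — a property of
the finite-resolution synapse, not a convergence failure; the
classification error and the likelihood trajectory are the robust
convergence measures.

## 7. Problem sizes

The package's reference task is deliberately desk-scale: `K = 10` neurons,
`N = 100` inputs, 5 prototype classes, 500 s of simulated training
(5 x 10^5 steps, ~5 x 10^4 network spikes), labeling with 20 and testing
with 100 presentations per class of 500 ms each. At these sizes a full
train-and-evaluate cycle takes on the order of ten seconds on one CPU, and
all stochastic checks hold with margin. The full-scale digit protocol
(`N = 576`, 5000 s, 1 s evaluations, 20 networks) is provided as an opt-in
script (`inst/scripts/reproduce_digits.R`) requiring the external IDX
files.

## 8. Known limitations

* Pure event-level abstraction: voltage waveforms, leaky-integrator
  membranes and circuit-level lateral inhibition are outside scope; the
  pulse scheme is abstracted into LTP/LTD event semantics.
* The binomial stationary description, and everything derived from it, is
  a small-`pi` asymptotic (see section 1).
* With `M` small the weight resolution itself limits how faithfully means
  can be represented (±1/(2M) at best, plus the stationary fluctuation).
* The free-energy decomposition is represented only through its KL
  diagnostic (`kl_divergence()`); Lagrange multipliers are absorbed into
  the excitabilities and not recoverable separately.
* The simulator allows at most one network spike per time step — exact for
  the model, but a difference from simulators that superpose spikes.
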