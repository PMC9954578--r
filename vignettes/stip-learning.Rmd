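---
title: "Spike-train inner-product learning: model, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-train inner-product learning: model, rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stipnet)
```

## The problem

Spiking networks carry information in discrete spike times, so the usual
mean-squared error over real-valued activations does not exist: the "output"
of a neuron is a sum of Dirac impulses. The approach implemented here maps
every spike train into a reproducing-kernel Hilbert space (RKHS) through a
spike-time kernel and does all comparison — the loss, the per-layer error
signals, the weight updates — through inner products in that space. The
inner products collapse to finite double sums over spike-time pairs, so the
continuous embedded signals never need to be evaluated.

## Model and assumptions

**Embedding.** Conceptually each train is convolved with a smoothing filter
φ; the inner product of two smoothed trains depends only on
κ(t_m, t_n) = ∫ φ(t−t_m) φ(t−t_n) dt, so the package works with the kernel κ
directly and never materializes φ. The four κ families and their default
widths (`kernel_spec`) are: Gaussian exp(−d²/2σ²) with σ = 40 ms, Laplacian
exp(−d/σ) with σ = 80 ms, inverse multiquadratic 1/√(d²+c²) with c = 30 ms,
and the α-kernel (d/σ)e^(−d/σ) with σ = 5 ms. The inverse multiquadratic is
implemented in its standard form 1/√(d²+c²); because the alternative
reading 1/(d²+c²) is also positive definite and plausible, it is selectable
via `imq_form = "squared"`.

The α-kernel satisfies κ(x, x) = 0, so it is not positive definite: its Gram
matrices need not be PSD, the RKHS "error" can be negative, and identical
trains are not detected as zero-distance. It is included because it is part
of the method's standard kernel set, but it is excluded from every
positivity property and test.

**Error.** With actual output trains a_i and desired trains d_i,

E = ½ Σ_i [ F(a_i, a_i) − 2 F(a_i, d_i) + F(d_i, d_i) ],

the closed-form expansion of ½∫‖h_oa − h_od‖²dt. For the Gaussian family
this identity is verified in the test suite against numerical quadrature of
the smoothed signals (φ is then the Gaussian with sd σ/√2 and amplitude
(s√π)^(−1/2), integrated on a grid extended 8 sd beyond the interval so the
infinite-domain closed form applies; agreement is required to 1e−3
relative).

**Update rules.** The derivation treats adjacent layers as linearly related,
h_l = W_l h_{l−1}. The resulting rules (`output_delta`, `bp_hidden_delta`,
`fa_hidden_delta`, `ba_hidden_delta`) consume only STIP matrices between the
stored spike trains of the simulated network. The linear relation is an
approximation for LIF dynamics — it is exact only for networks whose
weights select/merge trains — and the gradient tests exploit exactly that:
on 0/1 selection matrices the hidden and output trains are literal merges of
input trains, the relation holds exactly, and central finite differences of
the quadrature-evaluated surrogate error must match the implemented updates
to 1e−4 relative (they match to ~1e−12; the surrogate is quadratic in each
weight entry, so central differences are exact up to roundoff).

**Forward model.** Clock-driven LIF with a single state variable: per step,
decay by exp(−dt/τ), add the weighted presynaptic spikes of this step
(delta synapses), then threshold-test; a spike hard-resets V to the reset
value and propagates to the next layer within the same step. Defaults
follow the standard parameterization of this method: τ = 5 ms, threshold 5,
reset 0, interval T = 10 ms. There is no refractory period, bias current or
synaptic filter — the stated constants name a single time constant, and the
one-state-variable model is the simplest consistent reading; an
exponential-current synapse is deliberately out of scope. dt defaults to
1 ms (10 steps per interval), configurable; spikes live on the grid
t = 0, dt, …, T − dt, and off-grid input spikes are rejected rather than
silently rounded.

## Encoding, decoding, targets

* `poisson_encode`: per component and per step an independent Bernoulli draw
  with probability equal to the normalized intensity — the common
  clock-driven Poisson encoder, capped at one spike per step. Whether the
  original experiments drew counts instead of Bernoulli indicators is not
  decidable from their description; the Bernoulli reading keeps intensity 1
  exactly equivalent to "fire every step".
* `encode_label`: the labeled class's neuron fires "evenly" — interpreted as
  one spike per step (the maximal unambiguous reading), configurable via
  `n_spikes`; all other output neurons stay silent.
* `classify_spikes`: nearest template in RKHS distance, with softmax of the
  negated distances reported as scores (the argmax coincides with the
  argmin distance). Ties break to the lowest class index, which makes the
  all-silent output deterministic.

## Training loop

Mini-batch gradient descent with the defaults of the full-scale study
(η = 8e−5, batch 64, 150 epochs) in `train_config`; the synthetic task uses
η = 1e−3 because the network is three orders of magnitude smaller. Choices
where the method description is silent:

* **Batch aggregation**: per-sample ΔW averaged over the batch, applied once
  per batch (standard mini-batch semantics).
* **Synchronous updates**: all layers' ΔW are computed from the same
  pre-update weights, then applied together, matching the derivation and
  avoiding layer-order dependence.
* **Re-encoding**: inputs are Poisson re-encoded at every presentation
  (seed-controlled); `frozen_encoding = TRUE` encodes once for fully
  deterministic runs.
* **Metrics**: per epoch the mean RKHS loss and training accuracy are
  accumulated during the training pass (so they reflect the weights as they
  moved through the epoch), and test accuracy is evaluated after the epoch.
* **Divergence**: non-finite weights or `max|W|` beyond a guard abort with a
  message naming the epoch and layer (`divergence = "error"`) or truncate
  with a warning (`"stop"`). Backpropagation through spiking layers is
  known to be the unstable mode of this family; the guard makes that
  failure explicit instead of silently producing NaNs.

Internally, all on-grid trains are 0/1 neuron-by-step matrices and every
STIP is `S_p K S_qᵀ` with `K` the step-time Gram matrix precomputed once per
run; the public `stip_*` functions handle arbitrary off-grid times by the
double sum, and the test suite pins the two routes together to 1e−12.

## The synthetic task

`synthetic_task_spec` emulates the statistical shape of a pixel-based
image-classification pipeline without external data: binary class
prototypes (half the 20 components "on"), intensities 0.9/0.05 — high but
not saturating, so the Poisson encoder contributes genuine trial-to-trial
variability — 2% flip noise, 300 training and 90 test samples over 3
classes, prototypes at least 25% Hamming distance apart. These sizes let a
full training run finish in seconds on one CPU while leaving the task
non-trivial (chance is 33.3%).

What it does **not** emulate: the geometry and correlation structure of real
images, class overlap, and scale (784 inputs, 10 classes, 60k samples).
Passing tests therefore demonstrate that the rules assign credit correctly
and learn a separable rate-coded task — not that they reach any particular
accuracy on a real benchmark. Full-scale runs are supported through the
IDX reader and the CLI but take hours and external data.

One statistical subtlety is worth recording. Because flip noise is small,
the samples of a class are nearly identical, so a trained (or untrained)
network maps each class prototype to essentially one predicted label: a
single shuffled-label control run has an accuracy close to k/3 for some
k ∈ {0..3}, a lumpy variable with variance ≈ 0.074, not a binomial over the
90 test samples. The control tests therefore average the final accuracy
over five independent permutations and apply the chance band at that
variance; a single-run binomial band would be both too tight and
wrongly centred.

## Numerical choices

* Kernel evaluations are exact closed forms; no lookup tables.
* STIP of anything with an empty train is 0 (empty sum), and the RKHS error
  of identical sets is exactly 0 by construction (the expansion is computed
  termwise, not by cancellation of rounded quantities).
* Gram-matrix PSD checks use a −1e−9 eigenvalue floor to absorb symmetric
  eigensolver roundoff.
* Weight initialization and the feedback matrices are N(0,1), as in the
  full-scale study. With many inputs N(0,1) drives heavy saturation; the
  `scale` argument of `init_weights` exists for such experiments, with the
  faithful default untouched.
* Saved networks serialize doubles with 17 significant digits so a reload
  is bit-exact.

## Known limitations

* The linear spike-train relation behind the update rules ignores the LIF
  nonlinearity; as in the original method, learning on spiking layers is
  heuristic gradient descent on a surrogate, and BP mode inherits that
  family's instability at scale.
* Only dense fully connected feedforward networks; no convolution, pooling,
  recurrence, refractoriness or synaptic filtering.
* The α-kernel's degenerate self-similarity (κ(x,x) = 0) means the decoder
  and error functional lose their metric interpretation under that family.
* STIP cost is O(N_a N_b) per train pair; fine at 10 steps per interval,
  quadratic in rate for long intervals.
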