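---
title: "Entropy- and patience-based early exiting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy- and patience-based early exiting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The inference problem

A multi-exit classifier augments an M-layer transformer with an affine exit
head after every layer: head m maps the pooled hidden state s_m to class
probabilities p_m = softmax(W_m s_m + b_m). At inference time layers are
evaluated strictly sequentially on one instance at a time (batch size 1,
as in per-request serving), and after each layer an exit policy decides
whether to stop. Two quantities drive the decision at layer m:

* the **normalized entropy** H_m = −Σ_k p_m^k log p_m^k / log K, a
  base-invariant confidence score in [0, 1] (0 = one-hot, 1 = uniform);
* the **patience counter** P_m, the run length of consecutive layers whose
  argmax class agrees, reset to 1 on disagreement.

The hybrid policy exits at the first layer where H_m < τ **or** P_m ≥ P_t;
the final layer always emits regardless. Entropy-only exiting is the
special case P_t = M (since P_m ≤ m, patience can only be satisfied at the
last layer, where exit is unconditional anyway) and patience-only exiting
is the special case τ = 0 (the entropy test is strict and H_m ≥ 0, so it
never fires). Both degeneracies hold *trace-for-trace* in this
implementation and are asserted by the test suite and the acceptance
script.

## Decision-rule details that the formulas leave open

A few points are genuinely underdetermined by the usual way the rule is
written down; the package resolves them as follows, and the choices are
load-bearing for the degeneracy and composition properties above.

* **Ordering.** At each layer the patience counter is updated *first*
  (increment on agreement with the previous layer's argmax, else reset
  to 1), and the exit test H_m < τ ∨ P_m ≥ P_t is applied *after*. Folding
  the update into the non-exit branches instead would make the rule
  circular; the chosen ordering preserves both degeneracies and the
  min-composition property below.
* **Initialization.** P_1 = 1: a first prediction is a run of length 1,
  consistent with the reset value. Documented and tested consequence:
  P_t = 1 exits every input at layer 1.
* **Threshold semantics.** The patience test is implemented as P_m ≥ P_t
  rather than equality. Because the counter changes by at most +1 per layer
  and starts at 1, ≥ and = first fire at the same layer; ≥ is the safe,
  monotone form.
* **Strictness.** The entropy test is strictly `<`, so τ = 0 disables it
  even for exactly one-hot predictions.
* **Ties.** Argmax ties break deterministically to the lowest class index.
* **The emitted prediction** is the argmax of the exit layer's own
  distribution. Combining current and previous layers' predictions (e.g.
  majority voting over the run) is conceivable but no principled rule is
  forced by the setup, and any voting scheme would break the equivalence
  between the truncated forward pass and the policy applied to a stored
  trajectory; the current-layer rule keeps the two paths identical.
* **Indices.** Classes, tokens and layers are 1-based throughout, as is
  idiomatic in R.

Two structural properties follow and are tested property-style: the hybrid
exit layer equals min(entropy-only exit, patience-only exit) for every
fixed trajectory, because the patience dynamics do not depend on τ; and the
exit layer is monotone (non-increasing in τ, non-decreasing in P_t). An
independent brute-force reference (`exit_layer_oracle()`) recomputes the
exit layer per layer from scratch — entropy from its definition, run length
by backward scan — and is checked against the sequential implementation on
thousands of randomized trajectories.

## The trainable backbone

The backbone is a pre-norm transformer encoder: x ← x + Attn(LN(x)),
x ← x + FFN(LN(x)), with learned token and position embeddings, multi-head
scaled dot-product attention and a ReLU feed-forward block. Exit heads are
affine only — no intermediate nonlinearity — which is what makes the
parameter overhead M·(dK + K) exact and tiny relative to the backbone
(about 0.08% for a 12-layer, 768-wide encoder with nine classes; the
acceptance script recomputes the exact value). Parameter accounting is a
closed form over the embedding, per-layer attention/feed-forward/layer-norm
and optional pooler/final-norm shapes, and equals the instantiated model's
tally exactly; the encoder and decoder presets reproduce the published
109M/124M backbone counts.

No tensor/autodiff framework is used: forward and backward passes are
vectorised base-R matrix algebra with hand-derived gradients (layer norm,
softmax attention, residual branches, pooling, the weighted multi-head
loss). The gradient of every parameter group is verified against central
finite differences in the test suite, on a configuration that exercises all
optional components (token types, embedding layer norm, pooler, final layer
norm).

Defaults and their rationale:

* **Geometry** M = 6, d = 64, 4 heads, FFN 128, vocabulary 64, maximum
  length 32: the smallest geometry that still has genuinely distinct depth
  behaviour, and trains from scratch on one CPU in on the order of a
  minute.
* **Pooling** is `mean` for the tiny default. First-token pooling is the
  convention for encoder-style models whose inputs carry a dedicated
  classification token; the synthetic corpus has none, and mean pooling
  over a bag-of-evidence task gives every head direct access to the signal.
  `first_token` and `last_token` remain selectable (the decoder preset uses
  `last_token`).
* **Loss weights** w_m = m (`linear_cost`): the cost of reaching exit m is
  proportional to the m layers executed, so deeper (more expensive) exits
  carry proportionally more weight. A `uniform` scheme is retained as an
  ablation switch; the loss is invariant to rescaling the weights.
* **Optimization**: Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8), learning rate
  1e-3 — appropriate for a small model trained from scratch, where the
  1e-5-scale rates used when fine-tuning large pretrained backbones would
  barely move — batch 32, up to 15 epochs capped at 8 by default with
  plateau early stopping (relative improvement < 1e-3 for 2 consecutive
  epochs). Training is deterministic given the seed.
* **Numerical floors**: predicted probabilities are floored at 1e-12 inside
  the loss logarithm (a confidently wrong head yields a large finite loss);
  layer-norm variance uses ε = 1e-5; probability-vector validation
  tolerates 1e-6 on the sum so softmax output never trips it, while
  generated vectors satisfy the tighter 1e-9 construction invariant.

The final layer norm of the decoder preset is applied only before the
*last* exit head (it is defined after the last block; intermediate exits
tap the residual stream directly). Weights initialize from N(0, 0.02²),
biases at zero, layer-norm gains at one.

## Inference modes and evaluation

**Budgeted mode** fixes one exit m\* for all queries and executes exactly
m\* layers; m\* = M reproduces the conventional classifier on every input
(tested). `select_budget_exit()` picks the smallest layer maximizing
development-set accuracy — smallest on ties, i.e. the cheapest of the best
exits — which operationalizes choosing a budget from a per-layer accuracy
profile. **Dynamic mode** applies the policy per input. An instrumented
layer-call counter verifies that neither mode ever evaluates a layer beyond
its exit.

Efficiency is reported as the layer-count speed-up ratio
1 − Σ m_i / (N·M), affine in the mean exit layer and bounded by
[0, 1 − 1/M]; wall-clock timing is deliberately out of scope as
hardware-dependent. `grid_search()` evaluates every (τ, P_t) cell by
collecting each sample's full trajectory once and applying the policies to
the stored probabilities — licensed by the tested equivalence between the
truncated forward pass and the policy-on-trajectory path, and much cheaper
than re-running the network per cell. Its τ = 0 row and P_t = M column
reproduce the patience-only and entropy-only curves cell-for-cell.

## What the synthetic generators emulate — and what they do not

`generate_corpus()` produces a class-balanced K-class token corpus with a
controllable easy/hard mixture: token ids 1..K are class-evidence tokens;
easy records carry `evidence_strength` (default 3) copies of their class's
evidence token in the earliest positions, hard records one evidence token
at a random position plus, half the time, a distractor evidence token of
another class. Easy labels are recoverable by construction via the
bag-of-evidence rule, and hard records bound the achievable accuracy below
1, so accuracy ceilings and difficulty-dependent exit depth are both
exercised. Defaults (N = 2000, K = 4, length 16, vocabulary 64, half easy)
are the study condition used by the end-to-end tests: large enough for
stable accuracy estimates, small enough to train in about a minute on one
CPU.

`generate_trajectories()` is a model-free stand-in for a trained model's
per-layer head outputs: the logit of a sample's signal class grows linearly
with depth (`convergence_rate`, default 0.5) while all logits receive
Gaussian noise (`noise_scale`, default 0.5), and `label_flip_rate` (default
0.05) makes a trajectory converge to a wrong class, injecting irreducible
error. Expected normalized entropy then decreases with depth — the
empirical signature of trained multi-exit transformers — and expected exit
layers shrink as convergence accelerates ("simpler cases exit earlier"),
both asserted in the tests. With zero noise the entropy decline is strictly
monotone per sample; with zero rate and zero noise the distribution is
depth-constant and patience exits at exactly P_t.

What passing on these generators does **not** show: real corpora have
correlated tokens, class imbalance, miscalibrated heads and
out-of-distribution inputs, none of which the generators model, and the
backbone here is orders of magnitude smaller than production models. The
analytic results (parameter counts, degeneracies, metric identities) are
exact regardless; the end-to-end accuracy/speed-up numbers are evidence the
machinery composes correctly, not predictions for any real dataset.

## Problem sizes used by the checks

The test suite trains the tiny backbone three times (seeds 1–3) on the
default 2000-record corpus with a 1500/500 split, checks degeneracies on
10,000 random trajectories plus a trained model's held-out set, and runs
the oracle comparison on thousands of randomized instances; the whole suite
completes in a few minutes on one CPU. The acceptance script repeats the
analytic computations and one full train-evaluate cycle from scratch under
a caller-supplied seed.

## Known limitations

* Single-sequence classification only: no token-level exiting for
  generation, no cross-sample batching with heterogeneous exits (the
  per-instance contract is the point, but it leaves throughput-oriented
  batched serving unmodelled).
* No confidence calibration (e.g. temperature scaling); τ thresholds are
  applied to raw softmax entropies.
* No learned exit controllers; the policy is purely rule-based.
* The trainable backbone loads no published pretrained weights; the
  published geometries are supported for exact parameter accounting, not
  for running their checkpoints.
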