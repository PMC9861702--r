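---
title: "The ensemble multi-task synergy model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ensemble multi-task synergy model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demlr)
```

## The prediction problem

A drug-combination screen measures the effect of a drug pair (x, y) on a
cancer cell line r across a dose grid, from which several synergy scores are
derived under different null models: Loewe additivity (a drug is additive
with itself), Bliss independence (independent probabilistic effects), ZIP
(potency shifts of the dose–response curves), HSA (excess over the better
monotherapy) and the S score. These scores correlate only moderately with
one another — in large public screens the strongest pair (Bliss–HSA) reaches
rank correlations near 0.7 while the weakest (Loewe–S) is near 0.1 — so a
synergy call supported by several scores is far more credible than one
supported by a single score. Separately, a pair can be pharmacologically
risky: curated interaction databases record mostly *adverse*
drug–drug-interaction (DDI) types.

The model therefore treats a combination screen as a seven-task learning
problem: five synergy-score regressions, one synergy classification (Loewe
score strictly above 5), and one adverse-DDI classification. The inputs are
per-drug chemical descriptor vectors and a per-cell-line expression profile.

## Architecture

All tasks share a **hybrid ensemble layer** of M expert subnetworks (default
six, two of each kind), each producing a latent vector of dimension d:

* **dense**: two blocks on `CAT(dx, dy, cr)`;
* **bi-additive**: drug-specific two-block towers on `CAT(dx, cr)` and
  `CAT(dy, cr)`, outputs added elementwise;
* **bi-interaction**: the same double tower, but both the elementwise sum
  and the elementwise product of the two tower outputs are kept, passed
  through separate single blocks, and added.

A network *block* is `Dropout(BatchNorm(ReLU(Linear(x))))`. Normalizing
*after* the activation is unusual, but it is the composition this model
defines; `norm_before_activation = TRUE` in `deml_config()` switches to the
conventional order for experiments. Dropout probability defaults to 0.5 (the
full-scale setting).

Each task k has its own **gating network** — affine + ReLU, then an affine
map to M logits and a softmax — yielding simplex weights over the experts;
the fused task representation is the weighted sum of expert latents. With
`share_one_gate = TRUE` a single gate serves all tasks (the "one-gate"
ablation); with M = 1 the architecture degenerates to a share-bottom model.
The gate's output dimension is always M, the number of experts: the fusion
sum has exactly M terms, so a gate width equal to the task count (which a
reader might infer from the full-scale setting "{4096, 7}", where both
numbers coincidentally fit) would not type-check against Eqs for the fusion;
we treat the 7 as the task count and size the gate output as M.

**Prediction towers** are two blocks plus a final plain linear map;
classification towers emit two logits and a softmax.

### Defaults and their origins

| parameter | default | note |
|---|---|---|
| expert widths | 4096, 2048 | full-scale setting; d = last width |
| gate hidden width | 4096 | full-scale setting |
| tower widths | 2048, 2048 | full-scale setting |
| dropout | 0.5 | full-scale setting |
| loss weights | 1 (regression), 10 (classification) | balances the 0–1 probability scale against synergy-score units |
| smoothing ε | 0.1 | the source introduces ε without a value; 0.1 is the conventional label-smoothing setting |
| learning rate | 1e-4, batch 128, Adam | full-scale setting |
| patience | 100 epochs | full-scale setting; `max_epochs` defaults to 1000 (no ceiling is specified at full scale) |
| initialization | Xavier uniform, seeded | full-scale setting |

At desk scale (the test suite and the acceptance script) we shrink the
architecture to expert widths 64/32 (d = 32), gate hidden 64, towers 32/32,
and use learning rate 1e-3 with dropout 0.1: a rate tuned for 286k samples
and 4096-wide layers is conservative by an order of magnitude for networks
this small, and 0.5 dropout badly underfits 32-wide layers. These reduced
settings are the package's own choice for fast, reliable small-scale runs
and are stated wherever used.

## Training and evaluation protocol

Training records are **order-augmented**: each pair is presented as ⟨x, y⟩
and ⟨y, x⟩ with identical targets, so the network cannot learn an input-order
artifact. Validation and test predictions are computed in eval mode on both
orders and averaged (`predict_symmetrized()`), which makes them exactly
symmetric under drug swap. Early stopping monitors the total multi-task loss
on order-averaged, un-augmented validation predictions — mirroring test-time
behaviour; whether full-scale training monitored total or single-task loss
is not specified, and total loss is the natural choice for a jointly trained
model. The parameters returned are those of the best-validation epoch.

Cross-validation uses five near-equal folds; iteration i tests on fold i,
validates on the cyclically next fold and trains on the rest, so each sample
is tested exactly once. Metrics are averaged across folds with sample
variances and t-based 95% half-widths.

Metric definitions: RMSE; Spearman as the Pearson correlation of average
ranks (the textbook rank-difference formula is undefined under ties and
equals this form without ties); R² with the standard denominator
Σ(Yᵢ − Ȳ)². The printed source formula divides by Σ(yᵢ − Ȳ)², mixing
predictions with the mean of the actuals — we implement the standard form by
default because the quantity is called a coefficient of determination and is
compared against prior work using the standard form, and keep the printed
variant behind `printed_denominator = TRUE` for exact-formula comparison.
AUROC is the rank statistic (probability a random positive outranks a random
negative, half credit for ties), AUPR the area under the precision–recall
step curve. The decision cutoff is 0.5 (the class with the larger softmax
probability).

Screening follows the published protocol: a *support count* is the number of
the five predicted scores strictly exceeding 5 ("exceeding" ⇒ strict);
candidate filters keep combinations with synergy probability above 0.99 or
with all five predicted scores above 30, and drop combinations whose
predicted adverse-DDI probability is high.

## The synthetic cohort generator

`simulate_cohort()` provides fully in-silico data with the statistical
structure the model assumes:

* drug and cell-line features are noisy linear images of low-dimensional
  latent embeddings (latent dim 8; feature noise sd 0.05), so features carry
  recoverable low-rank structure as descriptor/expression panels do;
* each score is `scale · (shared_wₜ f + specific_wₜ gₜ) + N(0, noise_sdₜ)`
  where f and the gₜ are built from the symmetric latent terms
  `ex ⊙ ey`, `ex + ey`, `(ex + ey) ⊙ ec` and `ec` — symmetric under drug
  swap by construction, with the shared component inducing the positive
  cross-task correlations seen in real screens. The S-score analog gets a
  small shared weight (0.35) to reproduce its weak coupling to the others;
* the Loewe-analog intercept is calibrated on the realized sample so the
  positive fraction matches the 1:15 imbalance of the real cohort
  (`target_positive_rate = 1/16`);
* adverse-DDI status is a property of the unordered drug pair, constant
  across cell lines, at a 7% pair rate (matching the real label rate of
  roughly 20.9k/286k);
* noise is seeded per (unordered pair, cell line, replicate), so regenerating
  any sample — in either drug order — reproduces it exactly; replicates
  (`replicate_prob`, default 0 = the post-averaging cohort) carry independent
  noise and collapse correctly under `average_replicates()`.

What the generator does **not** emulate: heavy-tailed empirical score
distributions (noise is Gaussian), dose–response matrices and the score
formulas themselves (scores are primitives here, as they are inputs in the
real pipeline), feature-dependent DDI mechanisms (DDI status is assigned at
random per pair, so a model can only learn it by pair recurrence, which is
why small-cohort DDI AUROC hovers near chance), and batch effects. Passing
tests on this cohort therefore demonstrate that the implementation learns
the structure it was built for — not that it would reach any particular
accuracy on real screening data at the published scale.

A single master seed drives hierarchical sub-streams (entities, DDI pairs,
sampling, per-triple noise) so every component is independently reproducible.

## Numerical choices

* Batch normalization: ε = 1e-5, running-statistic momentum 0.1; at batch
  size 1 (and always in eval mode) running statistics are used, never batch
  statistics, so single-sample inference is well defined.
* Probabilities are floored at 1e-12 before logarithms in the
  cross-entropy, avoiding non-finite losses from saturated softmax outputs.
* Dropout is inverted (scaling by 1/(1−p) at train time), so eval mode is
  the identity.
* Scores exactly at the synergy threshold are labeled negative (strict
  inequality), keeping the positive set conservative; the same strictness
  applies to support counting.
* Replicate grouping treats (x, y) and (y, x) as the same pair; replicates
  with conflicting DDI labels are an error rather than silently resolved.
* Class imbalance is handled only through the 10× classification loss
  weight; no resampling is applied.
* Mini-batch order is reseeded per epoch from the training seed, making runs
  bit-reproducible; two runs with the same seeds produce identical histories.
* Checkpoints are a single RDS file holding the parameter tree (also
  flattened and keyed by module path) plus the configuration serialized as
  JSON; reload is bit-exact.
* Gradient correctness of the hand-written backward pass (including
  batch-norm and the product term of the bi-interaction expert) is enforced
  by finite-difference tests at relative tolerance 1e-5.

## Problem sizes used in the shipped runs

The test suite and `scripts/acceptance.R` use cohorts of up to 2,000–8,000
samples, the reduced architecture above, and 60–300 training epochs; the
learning-sanity checks require held-out R² ≥ 0.5 on the Loewe-analog task
and overfitting of a single 8-sample batch to under 10% of its initial loss.
These sizes were chosen so the full suite completes in minutes on one CPU
while still exercising every architectural component end to end.

## Known limitations

* The full-scale published setting (541/927-dimensional features, 4096-wide
  layers, 286k samples) is configurable but not practical in plain R on one
  CPU; the package's scope is the method, protocol and desk-scale validation.
* The generator's DDI labels are feature-independent (see above), so DDI
  classification performance on synthetic cohorts reflects pair memorization
  only.
* No GPU, no graph-based drug encoders, no attribution (SHAP) or enrichment
  analysis; screening rules operate on prediction tables regardless of how
  they were produced.
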