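---
title: "Greedy deep-network imputation for ordinal rating scales: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Greedy deep-network imputation for ordinal rating scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multi-informant ADHD assessments combine a complete block of continuous
measures — the 12 indices of a continuous performance test (CCPT), which
every participant finishes in the lab — with four ordinal rating scales
filled in at home and at school: the parent and teacher SNAP-IV forms
(26 items each) and the Conners' parent and teacher short forms (27 and
28 items), 107 items in total, each scored 0–3.  Questionnaires are
returned unevenly: the dominant missingness pattern is a participant
lacking an *entire* scale because one informant never returned the
form, with scattered item-level gaps on top.  Complete-case analysis
discards most of the cohort; classical fills (means, interpolation,
regression-based multiple imputation) distort the score distributions
they are meant to rescue.

`scaleimpute` implements a greedy, self-expanding imputation scheme:

1. Start with the feature set *F* = the 12 complete CCPT indices.
2. For every item that still has missing cells, train a deep multilayer
   perceptron to predict that item's observed responses from *F*, and
   record its held-out accuracy.
3. Select the item with the highest accuracy (ties break by canonical
   scale order), fill its missing cells with the model's predictions,
   and append the now-complete column to *F*.
4. Repeat from 2 until every item is complete.

The input width therefore grows by one per iteration: 12 features at
iteration 1, 12 + (k − 1) at iteration k, 118 at the last of 107
iterations.  The order in which items are selected is itself a result:
items chosen early are the ones the cohort's structure predicts best,
and the order's thirds (TOP / INTERMEDIATE / BOTTOM — 35/37/35 items
for the full registry) summarize which symptom domains and informants
carry a recoverable signal.

## The per-item network

Each candidate model is a fully connected network with one input layer,
15 hidden ReLU layers, and a 4-unit softmax output (one unit per Likert
score).  The hidden widths follow the input width *n* in three groups
of five: the first five layers have 2*n* units, the middle five *n*,
the last five ⌊*n*/2⌋ (clamped at 1).  Dropout is applied after every
hidden layer; the input features are not dropped, since with only 12
continuous features dropping inputs amounts to deleting the very signal
the imputation relies on.  Training minimizes categorical cross-entropy
with Adam, at the batch size set by `batch_mode`: the full training
set, mini-batches of 8, or single rows (stochastic).  Early stopping
watches the epoch-mean *training* loss and halts after
`patience_epochs` consecutive epochs without improvement, or at
`max_epochs`.

The reported per-item accuracy is honest: rows are split into training
and validation sets (stratified by score when every observed score has
at least two rows; the default holds out 20%), weights are only ever
updated on training rows, and the accuracy that drives the greedy
selection is computed on the held-out rows from the weight snapshot
with the best held-out loss.

### Numerical choices

A 16-layer stack whose widest layer has a few dozen units is far from
the regime in which deep networks are usually trained, and on cohorts
of a few hundred rows it fails in characteristic ways: the softmax sits
at the class priors for tens of epochs (so naive early stopping halts
before anything is learned), and under dropout the narrow ⌊*n*/2⌋
block suffers unit death from which ReLU cannot recover.  The trainer
therefore combines several standard stabilizers, all of which are
deliberate numerical choices of this package rather than tunable
hyper-parameters:

* **Orthogonal initialization** with the ReLU gain √2 and a small
  positive hidden bias (0.05), which preserve signal norms through the
  stack and delay unit death.
* **Global-norm gradient clipping** at 1.0: inverted dropout rescales
  surviving activations by 1/(1 − rate) per layer, and across 15
  layers rare mask configurations produce gradient spikes large enough
  to kill narrow layers in one Adam step.
* **Step-size decay**: the Adam learning rate (default 3 × 10⁻³)
  decays by 0.98 per epoch, floored at 10% of its initial value, so
  early-stopped runs still finish on annealed steps.
* **Curriculum dropout**: the dropout rate ramps linearly from 0 to
  its target over the first 30 epochs, letting the stack leave its
  initial plateau before the full regularization noise arrives;
  patience counting starts only once the ramp is complete, and the
  monitored training loss is smoothed (equal-weight exponential
  average) so minibatch noise is not mistaken for a stall.
* **Weight averaging**: an exponential moving average of the weights
  (0.99 per update) is what is evaluated and returned, smoothing the
  considerable dropout-induced oscillation of the raw iterate.
* **Restarts**: `n_starts` (default 2) independent initializations are
  trained and the one with the best held-out loss kept.  Degenerate
  items whose observed responses are a single value skip training
  entirely and return a constant model with accuracy 1.

Prediction takes the softmax argmax, with ties broken toward the lower
score — relevant only in the exactly-tied case (e.g. an all-zero
network), but fixed so results are bit-reproducible.  The continuous
CCPT columns are standardized with statistics fitted on training rows
only; merged item columns enter as raw 0–3 scores, which are already
bounded and commensurate.

## The synthetic cohort generator

The study's clinical data are not deposited, so the package ships a
generator that emulates its structure and makes every downstream stage
testable.  Each participant draws one latent trait per symptom domain
(inattention, hyperactivity/impulsivity, oppositional, cognitive
problems, ADHD index) from a unit-variance normal whose mean is shifted
in the CASE group by the domain's standardized effect size.  Parent and
teacher informants see correlated views of each trait (correlation
0.7 by default — informant agreement on these scales is moderate).  An
item's latent response is `loading × trait + noise` with loadings
drawn from U(0.5, 1.5), cut at fixed thresholds (0.5, 1.5, 2.5) into
the 0–3 score — a graded-response-style model whose default cutpoints
make control responses right-skewed, as symptom scales are in typically
developing samples.  Each CCPT index is a noisy random convex
combination of the domain traits scaled by `ccpt_loading` (default
0.8).  The default effect size is 1.5 on every domain, a strongly
separated clinical phenotype.

Missingness is layered on separately, with its own seed so one cohort
can receive many masks: each scale is blanked wholesale per participant
with a per-scale block probability, then surviving cells are blanked
independently at an item-level rate.  The default block probabilities
(SNAP-IV parent 0.355, SNAP-IV teacher 0.529, Conners parent 0.184,
Conners teacher 0.402) reproduce the completion rates of a large
two-site ADHD cohort, and the default item rate is 0.01.  Both layers
are missing-completely-at-random; an optional `mar_group_factor`
multiplies the CASE group's block probabilities to stress-test a
missing-at-random departure.  The mask generator never alters an
observed value, and CCPT indices are never blanked.

What the generator does *not* emulate: informant-specific rater biases
and drift, item-wording effects, the dependence of return rates on
family circumstances (the real mechanism is plausibly not MCAR), and
the empirical score distributions of the actual instruments.  Tests
passing on this generator show the machinery is correct and that the
method behaves as designed where signal is planted — not that clinical
data would yield any particular accuracy.

## Effectiveness evaluation

The evaluation mirrors the reference-versus-imputed protocol:
participants whose original records were fully complete form the
*reference* set; everyone else, after imputation, forms the *imputed*
set.  Both sets are classified CASE vs CONTROL with a radial-basis
support vector machine (cost 1, features standardized inside each
training fold) under stratified 10-fold cross-validation, and the two
fold-accuracy vectors are compared with a two-sided pooled-variance
(Student) t-test — an independent test, because the two sets are
disjoint participants.  A non-significant difference is the desired
outcome: imputation should neither destroy nor manufacture group
separation.  The degenerate case of two identical zero-variance fold
vectors is defined as t = 0, p = 1.

Two design notes.  The classifier settings are fixed and recorded in
the run object; the package deliberately does no model selection here,
since the evaluation is a yardstick, not a contribution.  And the
per-iteration classification track (`track_classification`) runs the
same classifier on all participants using the features merged so far,
which is the natural reading of a per-iteration discriminability curve.

## Baseline imputers

Three classical baselines share the completion-and-preservation
contract (no missing cells afterwards; observed cells bit-identical):

* `mean_impute()` — per-item observed mean, rounded half-up into 0–3.
* `interpolate_impute()` — within each participant and scale, linear
  interpolation over item position between nearest observed neighbours,
  nearest-value extension at the ends; a participant with an entirely
  missing scale falls back to the per-item means.  ("Interpolation" as
  an imputation method for item series is underspecified in general;
  positional interpolation within a scale is the reading implemented.)
* `multiple_impute()` — stochastic-regression chained equations:
  initialize by mean imputation, then cycle through items in canonical
  order for 10 rounds, regressing each item on all other columns by
  rank-tolerant least squares and redrawing its missing cells as
  prediction plus Gaussian residual noise, rounded into 0–3; `m`
  independent noise streams give `m` plausible completed tables.

## Scenario design for the property suites

Two constructions recur in the tests and are worth explaining.

*Matched-marginal planted items.*  Raw held-out accuracy confounds
predictability with marginal skew: an unpredictable but skewed item
scores its majority share, which can exceed a genuinely predictable
item's accuracy.  Ranking tests therefore construct every item as an
ordinal cut of a unit-variance latent — `(λ·x + ε)/√(λ² + 1)` with
common cutpoints — so all items share one marginal distribution and
accuracy differences reflect only the planted signal-to-noise λ.

*Graded loadings for order-stability tests.*  The sensitivity analysis
that drops oppositional (ODD) items and re-runs the loop checks that
the shared items keep their relative order (Spearman ρ).  That check is
only meaningful when the order is identifiable: items with no signal
are ordered arbitrarily, and no method keeps an arbitrary order stable
across two runs.  The stability scenario therefore gives all items a
log-spaced loading gradient (6 down to 0.3) and flags a subset as ODD.

*Problem sizes.*  The suites run at deliberately desk-scale sizes,
stated here as the package's chosen study conditions: order recovery
uses n = 300 with 12 items over 5 seeds (patience 5, mini-batches of
8, dropout 0.25); effectiveness preservation uses n = 400 with a
20-item registry subset, effect size 1.5, block missingness 0.3 and
item rate 0.05 over 10 seeds; completion/preservation sweeps 20 random
masks at n = 200.  The full 107-item loop trains O(107²/2) ≈ 5,700
networks and is supported (`run_pipeline()` with the full registry) but
is a long-running batch job, not a test.

## Known limitations

* The greedy criterion is raw held-out accuracy, as designed; on items
  with very skewed marginals it partly ranks skew rather than signal.
  The tier narrative inherits this caveat.
* With whole-scale block missingness, the information in a blanked
  scale is largely redundant with the always-complete CCPT block, and
  *any* imputation — including filling in the true held-back values —
  can fail to beat mean filling on downstream classification accuracy,
  because constant fills shrink within-class variance.  Cell-level
  reconstruction tells the two apart sharply (the network roughly
  doubles mean imputation's cell accuracy in the package's own
  experiments); downstream classification under heavy block
  missingness does not.
* Items observed fewer than 8 times cannot support a validated model;
  under the default policy they are deferred to the end of the order
  and filled from their observed mean, flagged `deferred`.
* The network trainer's stabilizers (clipping, warm-up, averaging) are
  fixed, not exposed; exposing them would invite tuning against the
  very accuracy the greedy loop treats as a measurement.
* Determinism holds for a fixed seed on a given platform/BLAS; the
  package's own RNG streams (C++ mt19937 for training, R's RNG for
  splits and masks) are isolated per call, so independent calls do not
  perturb each other.
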