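---
title: "Time-varying encoding of grip type and pulling force: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-varying encoding of grip type and pulling force: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`graspcode` implements an end-to-end analysis of how motor-cortex
populations encode two parameters of a delayed reach-to-grasp task — the
type of grip (side vs precision) and the level of pulling force (low vs
high) — from per-trial spike times, a trial-event table, and per-trial
pulling-force traces. This vignette explains each stage's model and
assumptions, the tunable parameters with their defaults, what the bundled
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## The task and its clock

Each trial follows one timeline: the hand rests on a switch; after 800 ms a
grip cue is shown for 300 ms; a 1,000 ms delay follows; the go cue (which
simultaneously instructs the force level) releases the reach; the object is
touched, pulled for at least 500 ms, released, and the trial rewarded.
Reaction time (RT) is go to movement onset; movement time (MT) is movement
onset to object touch. Because the grip instruction precedes the force
instruction by the full delay, grip can be prepared while force must be
programmed "on the go" — this asymmetry is the scientific point of most of
the analyses downstream.

All analyses use a per-trial clock in milliseconds with **movement onset as
the canonical alignment zero**; the analysis window is −2,000..+2,000 ms
around it.

## Synthetic sessions

The generator exists so every stage is testable without any recorded data;
it is first-class, tested code, not a fixture.

* `generate_trials()` fully crosses grip and force with
  `n_trials_per_condition` (default 30, the per-condition count used by the
  decoding analyses) correct trials per cell. RT and MT are drawn from
  truncated normal distributions (lower bound 20 ms); the defaults
  (RT 150 ± 48 ms, MT 123 ± 80 ms) are the reported behavior of the faster
  of the two recorded animals. Only means and SDs are constrained by the
  recorded behavior, so the truncated normal is a modeling choice.
* `neuron_spec()` defines an inhomogeneous Poisson unit with rate
  `rectify(baseline × profile(t) × (1 + g·s_g·[t ∈ W_g]) × (1 + f·s_f·[t ∈ W_f]))`,
  where `s_g, s_f ∈ {−1, +1}` encode the trial's grip and force. Effects are
  *multiplicative gains* rather than additive rates: rates stay nonnegative
  naturally and the induced auROC effect size is scale-free (a gain of 0.5
  gives a 3:1 preferred/anti-preferred rate ratio at any baseline).
* `make_population()` mirrors the empirically observed selectivity
  structure (grip-only, mixed, force-only, and condition-independent
  units). Under the `"static"` scheme every selective unit carries one long
  effect window from the grip cue through object release — the sustained
  code that produces temporally generalizing decoders. Under `"dynamic"`
  each unit gets a brief (300 ms) window whose onset is drawn uniformly
  across the perimovement period (−500..+800 ms), producing the banded,
  sequential selectivity heatmap and a decoder that does not generalize
  across time.
* Spikes are drawn by **thinning** against the per-trial rate maximum
  (taken on a 5 ms grid with a 2% safety margin), which is exact for the
  piecewise-smooth rates used here.
* `simulate_force()` produces traces that are ≈0 before pull onset, ramp
  linearly (default 150 ms) to a condition plateau (low 1, high 2,
  arbitrary units), decay after release, and carry additive Gaussian noise
  (default SD 0.05).
* One global seed expands deterministically into per-stage child seeds
  (`child_seed()`), so any stage can be reproduced in isolation.

What the generator does **not** emulate: trial-to-trial rate correlations
(each unit–trial is an independent Poisson draw), non-Poisson spiking
statistics (refractoriness, bursting), error trials, slow drifts in
excitability, and correlated noise across units. Passing tests therefore
demonstrate that the *statistics* behave as designed under their own
assumptions — not that recorded cortex satisfies those assumptions.

## Firing-rate estimation

`smooth_rates()` applies a causal exponential filter with decay constant
τ = 100 ms, evaluated every 20 ms; the kernel has unit area, so traces are
in spikes/s, and is truncated at 5τ (<1% mass loss). `bin_rates()` counts
spikes in 100 ms windows. Placing 51 centers across −2,000..+2,000 ms is
arithmetically incompatible with disjoint 100 ms bins (which would give
40); the only spacing consistent with both printed numbers is **100 ms
windows with centers every 80 ms** (20 ms overlap between neighbors), which
is what the package uses. Bins that would need data outside the recorded
trial are marked missing rather than padded.

## Single-unit selectivity

At every time bin, the auROC compares the firing-rate distributions of a
condition and its counterpart in the Mann–Whitney form
`P(rate_A > rate_B) + ½·P(tie)` over all trial pairs (class A is side grip,
or high force). 0.5 means complete overlap. Pointwise significance comes
from a label-permutation null of `|auROC − 0.5|` (two-sided — selectivity
direction is a sign, not a significance criterion), with 5,000 permutations
by default: the stated level α = 0.001 then still allows several null
exceedances per bin, where 1,000 permutations would demand beating every
single one. A unit *encodes* a parameter when at least two consecutive bins
are significant; classes are grip-only / force-only / mixed / none. Because
label permutations leave the per-bin trial ranks unchanged, the whole null
ensemble is computed as one matrix product over rank sums, which is what
makes 5,000 permutations cheap.

The independence battery then asks whether grip and force coding are
coupled across the population:

* **Permuted χ² marginal test** — per bin, the 2-D histogram of (force
  auROC, grip auROC) pairs (10 × 10 equal-width cells on [0, 1]²; empty
  expected cells skipped) is compared with the product of its own 1-D
  marginals; the null permutes force values across units, leaving both
  marginals intact. The binning is not dictated by anything in the task, so
  it is an exposed configuration value.
* **Covariance ellipse** — the orientation of the 95% normal-theory
  ellipse of the same scatter; an angle near 90° (principal axis vertical)
  is the signature of independent modulation directions.
* **ΔauROC strength correlations** — Pearson correlation across units
  between grip and force |auROC − 0.5|, per bin, against a null that
  shuffles both Δ matrices jointly across time *and* units (1,000 draws,
  without replacement); and the same statistic with force lagged
  −400..+400 ms in 20 ms steps (the rate-grid resolution), with
  significance again requiring two consecutive significant bins at a lag.

## Demixed PCA

The trial-averaged tensor `X[unit, grip, force, time]` is grand-mean
centered and split into four marginalizations: condition-independent
(time), grip (force-averaged conditional mean minus the time part), force
(symmetrically), and interaction (the remainder). The parts sum to the
centered tensor *exactly*; this identity is tested to machine precision.

Per marginalization, encoder/decoder axis pairs minimize
`‖X_φ − F D X‖² + μ‖F D‖²`: the full-rank ridge solution
`M = X_φ X′ (X X′ + μI)⁻¹` is rank-truncated through the SVD of `M X`. The
inverse is computed from the eigendecomposition of `X X′`, falling back to
the Moore–Penrose inverse when μ = 0 and the population is rank-deficient.
Components from all marginalizations are numbered globally by explained
variance (the reduction in squared residual attributable to each
component, as % of total centered variance), matching the conventional
global numbering of demixed components. With μ = 0 and a single active
marginalization the procedure reduces to PCA — the test suite checks the
subspaces agree to <1° principal angle. μ itself is not identified by the
analysis design, so `select_dpca_mu()` chooses it by 5-fold
cross-validated reconstruction error over a grid of 10⁻⁷..10⁻³ × total
variance; note that with observation noise the unregularized decoder
whitens against near-zero-variance directions, so a mild ridge markedly
improves planted-axis recovery.

Single-trial decodability of each marginalization uses a classifier on the
component projection: per time bin, held-out trials are assigned to the
nearest training-class mean, under a stratified Monte Carlo leave-group-out
cross-validation that holds out one trial per condition cell per iteration
(the smallest stratified held-out group; 100 iterations). Chance is an
ensemble of 100 label-shuffled runs; a bin is significant when the actual
accuracy exceeds **all** 100 shuffled accuracies (the strictest reading;
exceeding the 99th percentile is the configurable alternative) for at
least 10 consecutive bins. The "first significant" component of a
marginalization is its lowest-numbered component with a nonempty mask;
interaction components routinely end up with none, and are then reported
as not significant. Ten components per marginalization are retained by
default — enough that marginalization variance totals are effectively
exhausted at these population sizes.

## Cross-temporal decoding

Per 100 ms bin, a linear maximum-margin classifier (SVM, linear kernel,
default cost 1 — the classifier family is fixed by the design, the kernel
and cost are the field-default choice) is trained on 25 and tested on 5
trials per class, over 50 random splits; features are standardized per bin
using training trials only, and the same per-bin scaler is applied to test
trials. The package deliberately implements the 25/5 random-split scheme
repeated 50 times as the operative procedure (a k-fold description of the
same analysis would tie the fold count to the trial count and cannot
produce the stated 25/5 split sizes at 30 trials per class). Training at
bin *i* and testing at bin *j* for all pairs yields the cross-temporal
matrix; its diagonal reproduces the per-bin time course up to repetition
noise.

A train/test pair is **static** when three conditions all hold:

1. it belongs to an 8-connected supra-threshold cluster (pointwise
   threshold: 95th percentile of the shuffled-label null per cell; cluster
   mass: Σ(accuracy − chance)) whose mass exceeds the 99th percentile of
   the null maximum-cluster-mass distribution — the cluster test runs on
   the full matrix rather than per train-row, the less assumption-laden of
   the two readings;
2. its accuracy exceeds the 99th percentile of its own 1,000-iteration
   shuffled-label null; and
3. both of its diagonal bins pass a permutation test at p < 0.01 after
   Bonferroni correction over the diagonal. For this test the p-value is
   the raw null-exceedance proportion: with any finite null ensemble an
   add-one-corrected p can never clear a Bonferroni threshold below
   1/n_null, whereas an accuracy that beats every shuffle legitimately
   reports p = 0.

Cells surviving all three are kept only in runs of ≥2 consecutive cells
along the *test*-time axis (the generalization index is a function of test
time). The **generalization index** for epoch E at test bin t is the
fraction of train bins inside E whose pair (train, t) is static, with
preparation = [mean cue onset, mean go] and execution = [movement onset,
mean release] in movement-aligned coordinates. An all-static matrix gives
GI ≡ 1, an all-empty one GI ≡ 0.

The shuffled-label null matrices default to one split repetition per
iteration: the null needs the distribution of chance-level accuracies, and
spending 50 repetitions per iteration would multiply the cost 50-fold
without changing that distribution appreciably.

## Behavior and force traces

`behavior_summary()` reports RT/MT means and SDs per subject and compares
two subjects with a Mann–Whitney rank-sum z (normal approximation, tie
corrected; checked against an exhaustive pairwise oracle and the reference
implementation in the tests). `force_dpc_correlation()` correlates each
trial's force trace (normalized to unit peak) with its single-trial
projection on the leading force component and the leading
condition-independent component, taking `R² = (max |r|)²` over lags up to
±500 ms (the lag cap is not dictated by the design; it generously covers
the RT/MT scale and is configurable). Significance bounds come from random
circular time-shifts of the force trace, which preserve its
autocorrelation — a plain trial shuffle would overstate significance for
slowly varying traces. A two-way ANOVA on R² (component type × force
level) tests whether the condition-independent component tracks the force
signal more closely than the force component, as the phasic force coding
observed in cortex would predict.

## Problem sizes and determinism

The package's own validation runs at the study's stated conditions where
those exist: 30 trials per condition, ~100-unit populations, a 3:1
preferred rate ratio (gain 0.5), α = 0.001 with two consecutive bins,
50 × 25/5 decoding splits, 51 bins over ±2 s. Null ensembles in the
static/dynamic comparison use 200 shuffled iterations; permutation and
shuffle counts elsewhere follow the stated 1,000 (5,000 for pointwise
auROC significance, to resolve α = 0.001 with slack). Every stochastic
step takes a child seed derived from one global seed, and fixed seeds give
bit-identical trials, spikes, force traces, and decoding matrices.

## Known limitations

* The Poisson generator cannot express trial-to-trial covariability, so
  decoder accuracies on synthetic data are optimistic relative to recorded
  populations of the same size.
* The χ² marginal test needs enough units to fill a 10 × 10 histogram;
  below ~20 units it refuses to run rather than return an unstable answer.
* The cluster test's null assumes exchangeability of condition labels
  across trials, which the generator satisfies by construction; recorded
  sessions with behavioral drift would need a blocked shuffle.
* Reading the public NIX/HDF5 release of the recorded sessions is out of
  scope for the core package; analyses accept any data source that can be
  expressed as the trial-table + spike-data text formats of `read_session()`.
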