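---
title: "Measuring task-driven dimensional stretching of neural representations"
author: "dimstretch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring task-driven dimensional stretching of neural representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

When a cue tells an observer which stimulus dimension matters — the color of
a dot field, or its direction of motion — does the neural code *stretch*
along that dimension, making task-relevant differences between stimuli more
discriminable and task-irrelevant ones less so? `dimstretch` implements the
full analysis chain for asking this question of multi-site spike-time
recordings from a cued color/motion categorization task, together with a
synthetic-recording generator that makes every stage testable end-to-end,
and a scaled-down rendered-task arm in which a stacked recurrent network
learns the same task from pixels and its hidden layers are analysed with the
same machinery.

The stimulus space is a 4 x 4 grid: four color values crossed with four
motion directions, drawn from 7-step physical axes whose middle steps are
ambiguous (near the category boundary); 16 analysed stimuli tile the grid
and 5 ambiguous stimuli sit at or near the origin and demand a withheld
response in both contexts.

## Dissimilarity measures

Two spike-timing measures and three rate measures are implemented behind one
interface (`multisiteDistance()`), pooled over recording sites:

* **ISI-distance.** Both trains are augmented with auxiliary spikes at the
  window edges; at time $t$, $x_{\mathrm{isi}}(t)$ is the length of the
  augmented-train interval containing $t$ and the profile is
  $I(t) = |x_{\mathrm{isi}}(t) - y_{\mathrm{isi}}(t)| /
  \max(x_{\mathrm{isi}}(t), y_{\mathrm{isi}}(t))$,
  a piecewise-constant function averaged exactly over the window. It is
  sensitive to the relative pattern of interspike intervals, not to absolute
  spike placement.
* **SPIKE-distance.** Combines the distances from each spike to the nearest
  spike of the other train, normalised by the local interval structure; the
  profile is piecewise linear and again averaged exactly (trapezoids per
  segment). It additionally carries absolute timing information.
* **Rate coding.** Each trial is reduced to a per-site spike-count vector
  within the window and compared by Euclidean distance, cosine distance, or
  1 − Pearson correlation. An undefined correlation or cosine (zero/constant
  count vector) propagates as a missing value rather than a silent zero,
  so it can never bias an RDM average toward similarity.

Both timing profiles are exact piecewise algebra, not quadrature: segment
breakpoints are the union of augmented spike times, and every segment is
integrated in closed form. The test suite holds them against an independent
dense pointwise oracle to 1e-8 and checks symmetry, translation invariance,
boundedness, and the empty-train conventions (an empty train is the
two-edge-spike train whose single interval spans the window). Spikes outside
the analysis window are dropped *before* augmentation; windows are closed
intervals; duplicate spike times are rejected when data are parsed.

## From trials to RDMs to scores

Only one stimulus is shown per trial, so a session-level representational
dissimilarity matrix (RDM) is built from cross-trial pairs: entry $(i, j)$
is the mean multi-site distance over sampled pairs of trials showing
stimuli $i$ and $j$ within one session and task context
(`buildSessionRDM()`). All cross-trial pairs are used up to a cap of 200
per cell; beyond that a subsample is drawn with a seed keyed to the session
id, which makes the estimate reproducible and invariant to the order in
which trials are stored. Rate measures use a fixed seeded subset of 30
sites for comparability across sessions. A stimulus without trials yields
missing entries, never zeros.

RDMs are compared by Spearman rank correlation over the 120 off-diagonal
upper-triangle cells (`rsaSpearman()`), excluding cells missing in either
matrix and requiring at least 3 comparable cells. Rank correlation makes
every downstream score invariant to monotone transforms — in particular to
the $1 - e^{-c\,d}$ wrapper and its scale constant $c$ in the model
geometries below, which is asserted in the tests rather than assumed.

The reference geometry is the experimenter-intended stimulus arrangement:
$E(a,b) = 1 - \exp(-\sqrt{|a_x-b_x|^2 + |a_y-b_y|^2})$ on the grid
coordinates. Time-resolved analyses slide a 50 ms window in 10 ms steps
(`slidingWindowRSA()`), summarising across sessions with a t-based 95%
confidence interval; the candidate-measure comparison
(`measureComparison()`) scores every measure per session against the
reference and tests the measure factor with a one-way ANOVA plus
Bonferroni-corrected paired t-tests.

## The model-free stretching test

For each dimension, the 24 mismatch pairs share their coordinate on the
other dimension and differ on the mismatching one (4 shared values x
$\binom{4}{2}$ pairs; `mismatchPairs()`). "Mismatch" means a differing grid
coordinate — the only reading that yields 24 pairs on a 4 x 4 grid.
`stretchingTable()` pulls these cells from per-context RDMs and
`stretchingTest()` reports (a) paired two-tailed t contrasts
$D_c^{\,c} - D_c^{\,m}$ and $D_m^{\,m} - D_m^{\,c}$ and (b) the
task x mismatch-dimension interaction from a linear model with grouping-unit
and pair intercepts. Pair intercepts matter: mismatch pairs differ in their
true geometric separation, and leaving that variance in the residual makes
the F test conservative. With pair and unit intercepts the test holds its
nominal size — on the null generator preset the suite measures a type-I
rate of ~5% over 200 seeded replicates, and power ~100% on the modulated
preset. With only two subjects a richer random-effect structure is not
estimable, so grouping units enter as fixed intercepts. The layered variant
adds a continuous layer covariate and reports the three-way interaction.

## The attention-weighted geometry model

The model-based analysis assumes a psychological space in which attention
reweights dimensions:
$AE(a,b) = 1 - \exp(-c\sqrt{w\,|a_r-b_r|^2 + (1-w)\,|a_i-b_i|^2})$
with $w \in [0, 1]$ on the relevant dimension. Throughout the package $w$
is parameterised as the weight on the *motion* dimension, so fitted weights
read directly as motion-attention in both contexts. Fitting
(`fitAttention()`) maximises the Spearman correlation with a data RDM over
a grid of $w$ from 0 to 1 in steps of 0.01 (matching the precision at which
weights are conventionally reported); $c$ is fixed at 1 because rank
correlation is provably invariant to it, and searching it would add a
spurious free parameter.

Because ranks are piecewise-constant in $w$, the grid search genuinely
ties: a run of adjacent weights can score identically (even data generated
exactly from $AE(0.8)$ give a tied run of about [0.80, 0.83]). The fit
returns the midpoint of the longest tied run and records the tie — a
deterministic rule biased toward neither extreme. Weight-recovery tests
therefore assert $|w_{\mathrm{fit}} - w_{\mathrm{true}}| \le 0.05$, not
exact equality.

`crossvalAttention()` runs 5-fold cross-validation separately per subject
and context: trials are stratified by stimulus within each session (seeded,
so every fold RDM is complete whenever trials-per-stimulus >= k), the
training RDM pools the k−1 training folds, and the fitted geometry is
scored on the held-out fold's RDM — 20 held-out evaluations for 2 subjects
x 2 contexts. The baseline model is identical but trains on two folds from
each context (trials pooled, not context-averaged — the simplest reading of
a mixed-context fit; a pooled training RDM is built from the union of those
trials). `modelComparison()` tests cognitive vs baseline held-out scores
with a fixed model factor and subject intercepts (reproducing the
$F(1, 37)$ degrees-of-freedom structure for 40 scores), or with continuous
training-step and layer covariates and simulation intercepts in the layered
design.

## What the synthetic generator plants, and what it does not

`simulateCohort()` generates seeded multi-session recordings whose
*expected pairwise distances* follow $AE$ at a per-context true weight —
geometry is planted directly at the level the analyses consume, rather than
via biophysics, which makes parameter recovery a well-posed test. Each site
carries an independent random unit direction in the (color, motion) plane,
plus a small session-fixed per-(site, stimulus) tuning distortion scaled by
the noise level; the site-pooled |projection| approximates the planted
weighted norm with O(1/sqrt(sites)) angular sampling error, so single
20-site sessions reach rank correlations of ~0.85-0.98 with the planted
geometry while the seed-averaged (expected) RDM exceeds 0.99. Independent
site directions also keep sessions exchangeable draws rather than copies
of one direction set — which is what makes the stretching test's F
statistic well calibrated on the null preset. In timing mode a site fires a
template train (24 spikes over the 0.6 s window) whose alternating
interspike intervals are modulated in proportion to the stimulus's weighted
projection; spike counts are identical across stimuli at zero noise and
jitter stimulus-independently with noise, so rate measures carry no
stimulus signal by construction. In rate mode counts are linear in the same
projection with additive noise and uniform spike timing. The single `noise`
parameter (spike jitter as a fraction of the template interval, or count
noise as a fraction of the base count) is a modeling choice: the noise
spectrum of real recordings is unknown, and no claim is made that this
one-knob family matches it.

Consequences for interpretation: passing tests show the *pipeline* is
correct and well-calibrated under planted geometry — they do not show that
real cortex stretches, nor that real noise resembles interval jitter.
Presets: `modulated`/`pfc-like` (weights 0.8/0.2 tracking context), `null`
(0.5/0.5), `mt-like` (0.9 both contexts), `v4-like` (0.1 both), and a
`paperScale` switch that raises the cohort to ~53 sessions per subject.
Every draw is keyed by (master seed, subject, context, session, trial,
site), so any single trial is reproducible in isolation.

## The rendered-task arm

`renderTrial()` draws the trial structure from pixels: fixation point
(0.5 s), a cue whose shape encodes the context (cross/quatrefoil for
motion, circle/triangle for color), then a field of same-colored dots
drifting with 100% coherence, positions re-randomised per trial. The
scaled default is 32 x 32 frames and 30 frames per trial (3/7/20,
preserving the 0.5 s : 1 s : 3 s phase proportions); the 7-step color axis
interpolates green to red and the motion axis spans up to down through
horizontal (exact hues and angles are config constants, documented as
assumptions). A `full` preset carries the full-scale constants (270 frames
at 60 frames/s, 6 layers x 1000 cells, 256-unit head, learning rate 1e-5)
for parity.

The frozen pretrained image network of a full-scale pipeline is replaced by
a fixed feature extractor: each frame is average-pooled to 8 x 8 per
channel, and two motion-energy-style channels are appended — the per-frame
temporal difference of the pooled image, and a global optical-flow estimate
(the least-squares solution of the brightness-constancy equation between
consecutive luminance frames). A seeded random projection is also
available. The claim under test is representational stretching in the
recurrent stack, not object-recognition fidelity; a coarse pooled image
plus first-order motion energy is the minimal front-end that makes both
task dimensions reliably available to a small network — with pooled pixels
alone the network settles into a color-only policy on a substantial
fraction of training seeds before ever discovering temporal structure. The stacked
LSTM (3 layers x 64 cells by default), two-stage linear head with softmax,
cross-entropy on the trial-final output (a per-frame loss mode is also
provided, since either reading of a sequence loss is defensible), Adam with
gradient-norm clipping at 5, and batch size 1 (trial-by-trial learning) are
implemented in base matrix code and verified against numerical gradients to
1e-4. Training uses a stepped learning-rate schedule (1e-3, x0.3 at epochs
16 and 24): the network typically discovers the color shortcut first and
only later learns motion direction; the decay consolidates performance
after that breakthrough instead of oscillating. Checkpoints on a held-out
set are taken once per epoch (configurable down to steps), and the
best-checkpoint parameters are retained.

`layerRDMs()` maps analysis time onto frames (at 60 frames/s a 0.05 s bin
is 3 input images and the 0.25 s period is 15; the scaled clock is 30
frames per 4.5 s trial), averages each layer's hidden state over the bin,
and builds per-layer, per-context RDMs from mean cross-trial Euclidean (or
cosine) distances — directly consumable by the stretching and attention
machinery above.

## Numerical choices and degenerate inputs

* Exact segment integration everywhere in the timing measures; no
  quadrature error enters the scalars.
* Ties in Spearman ranks use average ranks; tied argmax runs resolve to
  midpoints (recorded).
* Undefined rate-vector comparisons (constant/zero counts) are missing
  values, excluded from averages and from RSA cells.
* An RDM cell with no trial pairs is missing; RSA requires >= 3 comparable
  cells; the attention fit refuses all-constant RDMs.
* Degenerate ANOVA inputs (all-equal scores) report F = 0, p = 1 rather
  than NaN.
* Seeds: all randomness flows through explicit seed arguments folded
  bytewise into 31-bit streams; the caller's RNG state is never disturbed.

## Problem sizes used by the test suite

The suite exercises the full pipeline at deliberately small sizes chosen as
the smallest cohorts at which each property is stable: calibration and
recovery checks use single sessions of 10-20 sites x 2-10 trials per
stimulus; the type-I/power simulations run 200/50 seeded replicates of a
2-subject, 8-site, 4-trials-per-stimulus cohort; the task arm trains on
1008 trials (24 per stimulus and context) of 30-frame 32 x 32 trials for
20-26 epochs and evaluates 168 held-out trials. The `paperScale` preset and
`full` task config restore study-scale sizes for users with the compute to
match.

## Known limitations

* The generator's timing code modulates interval patterns only; it does not
  emulate bursting, oscillations, adaptation, or correlated noise across
  sites, and its one-parameter noise family is a convenience.
* Two subjects cannot support random-slope inference; grouping units enter
  as fixed intercepts, as in the degrees-of-freedom structure reported for
  such designs.
* The scaled task arm shows qualitative, not quantitative, correspondence
  with a full-scale pipeline: a pretrained deep front-end, 6 x 1000
  recurrent cells and hour-scale training are out of scope by design.
* Noise-ceiling estimation, cross-validated RDM distances and whitened RDM
  comparison statistics are deliberately not implemented.
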