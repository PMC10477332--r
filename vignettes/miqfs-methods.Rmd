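---
title: "Hybrid MIC–QPSO feature selection: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid MIC-QPSO feature selection: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miqfs)
```

## The problem

Multichannel EEG classification problems (for example separating depressed
patients from healthy controls on resting-state recordings) typically combine
small sample sizes — a few dozen subjects, segmented into a thousand or so
epochs — with very high feature dimensionality: five frequency bands per
channel, several feature families per band, hundreds of columns in total.
Irrelevant columns hurt accuracy and redundant ones waste classifier capacity,
so feature selection is a first-class part of the modelling, not a
convenience.

`miqfs` implements a two-stage hybrid selector:

1. **Filter stage.** The maximal information coefficient (MIC) of each feature
   with the class label removes *irrelevant* features (MIC < 0.2); among the
   survivors, pairwise MIC removes the less label-relevant member of every
   strongly related pair (MIC > 0.8). MIC detects arbitrary functional
   dependence, not just linear correlation, which is what justifies using one
   statistic for both rules.
2. **Wrapper stage.** Quantum-behaved particle swarm optimisation (QPSO)
   searches jointly over the remaining binary feature mask *and* the
   Gaussian-kernel SVM hyperparameters $(C, \sigma)$, scoring each candidate
   with a dimension-aware fitness
   $$ f = \varphi(d)\,\mathrm{CA} + \bigl(1 - \varphi(d)\bigr)\,\mathrm{DR},
      \qquad \varphi(d) = \frac{9 + e^{-d/100}}{10}, $$
   where CA is inner cross-validated accuracy, DR the dimension-reduction
   rate, and $d$ the original (pre-filter) feature dimension. $\varphi$
   decreases from 1 at $d = 0$ towards 0.9, so dimensionality reduction never
   carries more than 10% of the fitness but gains weight exactly when the
   original problem is high-dimensional.

## EEG feature engineering

An epoch (default 10 s at 256 Hz) of each channel is decomposed by a six-level
discrete wavelet transform and reconstructed into the five clinical bands.
At 256 Hz the dyadic detail levels line up with the band edges: gamma = D2
(32–64 Hz), beta = D3 (16–32 Hz), alpha = D4 (8–16 Hz), theta = D5 (4–8 Hz),
delta = D6 + A6 (0–4 Hz). Two choices here were genuinely open:

* **Mother wavelet.** Nothing pins the filter; we default to `db8` because its
  sharper transition bands keep ≥ 90% of a band-centred sinusoid's energy in
  its own band reconstruction (a 10 Hz tone keeps 93% in alpha with `db8` but
  only 82% with `db4`, the rest leaking into theta and beta). `db2` and `db4`
  remain selectable for users who want shorter filters.
* **Top detail level D1** (64–128 Hz) is folded into the gamma reconstruction.
  Clinical gamma interest stops near 64 Hz and recordings of this kind are
  low-pass filtered near 50 Hz, so D1 is essentially empty in practice — but
  folding it in makes the five bands an *exact additive partition* of the
  epoch: the band series sum to the input to machine precision, which the test
  suite asserts. Features are computed on the band-reconstructed time series
  (not on raw coefficients) so time-domain statistics keep the original
  sampling rate and epoch length.

Per band series, five families are computed:

* **C0 complexity** — zero every spectrum bin whose power is at or below the
  mean bin power, invert what is kept, and report the residual energy
  fraction; in $[0,1]$, 0 for a dominant-line signal.
* **Approximate entropy** — Pincus' template-matching statistic with the
  standard $N - m + 1$ template normalisation, natural logs, self-matches
  included; defaults $m = 2$, $r = 0.2\,\mathrm{SD}$. (One published variant
  prints $N - m - 1$ as a count denominator; we use the standard form, under
  which a constant series gives exactly 0 and a strict alternation is 0 up to
  an $O(1/N)$ finite-size correction.)
* **Higuchi fractal dimension** — slope of $\ln L(T)$ against $\ln(1/T)$ using
  the standard curve-length normalisation, $T = 1..k_{\max}$, default
  $k_{\max} = 8$; ≈ 1 for smooth curves, ≈ 2 for white noise.
* **Hjorth parameters** — activity is the centred population variance;
  mobility and complexity are formed from the *uncentred* mean squares of the
  first and second difference signals. This is the spectral-moment form
  ($\sqrt{m_2/m_0}$, $\sqrt{m_4/m_2}/\sqrt{m_2/m_0}$): difference signals of a
  stationary epoch are zero-mean up to edge effects, and the uncentred form
  keeps hand-checkable identities exact (e.g. $x = (1,-1,1,-1)$ has mobility
  exactly 2 and complexity exactly 1).
* **Mean PSD** — $\frac{1}{N}\sum |X_k|^2$ with the unnormalised DFT, which by
  Parseval equals the epoch energy $\sum x_n^2$.

For a 19-channel montage this gives 95 columns per scalar family, 285 for
Hjorth (three parameters), and 665 for the full fusion.

Degenerate band series (constants, all-zero signals) make several of these
statistics undefined; `extract_feature_matrix()` either raises (default) or
fills 0 with a warning (`on_degenerate = "zero"`), a policy choice exposed
because batch extraction over thousands of epochs should be able to survive a
flat channel.

## The MIC estimator

Only the defining maximisation is fixed by the method: over all grids with
$X \cdot Y < B$ cells, $B = \lfloor n^{0.6} \rfloor$, take the grid mutual
information normalised by $\log_2 \min(X, Y)$. The search itself follows the
MINE approximation: equipartition one axis into $q$ rows (never splitting tied
values), then optimise the other axis by a segmentation dynamic program whose
per-column weights are additive; candidate cut points are clumps of tied
values, merged into at most $c \cdot k_{\max}$ superclumps ($c = 15$) when
numerous. Both orientations are searched and the maximum taken, which makes
the estimate exactly symmetric; the whole computation is deterministic, so
identical inputs give bit-identical outputs. The $2\times2$ grid is always
admitted even when $\lfloor n^{0.6}\rfloor < 4$ would forbid it, so very small
samples still receive a meaningful score. Logs are base 2 throughout.

An exhaustive estimator (`mic_exhaustive()`, $n \le 14$) enumerates every
tie-respecting partition pair and is used purely as a test oracle: the DP
estimate must never exceed it and must match it on functional data, which the
suite checks over randomised instances.

Tie handling, the minimum grid, and the rounding of $B$ are our choices; they
matter only in corner cases but are asserted by tests so they stay stable.

## Filter stage

Removal uses strict inequalities as stated: irrelevant iff
$\mathrm{mic}(x_i, y) < 0.2$, redundant iff $\mathrm{mic}(x_i, x_j) > 0.8$.
The pairwise rule alone is order-dependent when redundancy chains occur
($a \sim b$, $b \sim c$, $a \not\sim c$), so the implementation resolves
chains greedily: sweep candidates in descending label-relevance; each accepted
feature eliminates every not-yet-accepted feature whose pairwise MIC with it
exceeds the threshold. This is deterministic, keeps the most relevant
representative of each redundancy group, and reduces pairwise MIC evaluations
to accepted-vs-candidate pairs. Exact relevance ties break towards the lower
column index.

## QPSO

The optimizer is position-only: per particle $i$ and dimension $j$, an
attractor $P = \varphi_j\,\mathrm{pbest}_{ij} + (1-\varphi_j)\,\mathrm{gbest}_j$
with $\varphi_j \sim U(0,1)$ drawn per particle and dimension; the new
position is $P \pm \alpha\,|\mathrm{mbest}_j - x_{ij}|\ln(1/u)$ with the sign
negative when $r \ge 0.5$, $u, r \sim U(0,1)$ per particle and dimension, and
$\alpha = 0.5 + 0.5\,(T_{\max}-t)/T_{\max}$ decaying linearly from 1.0 to 0.5.
Three details the formulation leaves open:

* **Bound handling** — positions are clamped to the box after the update.
* **$\ln(1/u)$ guard** — $u$ is floored at $10^{-12}$.
* **Optimisation sense** — the update and best-keeping rules are written for
  minimisation; the wrapper's fitness is maximised via internal negation
  (`sense = "maximize"`), keeping the best-keeping rules literal.

The global best is monotone by construction, the history has one entry per
iteration, and a fixed seed reproduces the run bit for bit. Reference budgets
are $N = T_{\max} = 200$; tests and the examples below use reduced budgets
because the benchmark problems are tiny.

## Wrapper stage

A particle has $n_{\text{features}} + 2$ dimensions: mask coordinates in
$[0,1]$ where a value $\ge 0.5$ selects the feature (the boundary counts as
selected, matching the half-open selection interval $[0.5, 1)$), then $C$ and
$\sigma$ within configurable bounds (defaults $[0.01, 100]$ each, linear
scale; a log-scale mapping is available). Accuracy is estimated by stratified
inner $k$-fold cross-validation (default $k = 3$) of an SVM with kernel
$\exp(-\lVert x - z\rVert^2 / 2\sigma^2)$; the solver is libsvm via `e1071`,
with the bandwidth mapped as $\gamma = 1/(2\sigma^2)$. Features are
standardised per fold with statistics fitted on the training portion only, so
$\sigma$ has a stable meaning across masks. The inner fold assignment is
seeded per fitness call, making fitness a deterministic function of the
particle — without this, pbest/gbest bookkeeping would chase fold noise.
DR is defined as $1 - |\text{mask}|/n_{\text{candidates}}$ (the method leaves
DR's normalisation open; this choice puts it on the same $[0,1]$ scale as CA,
and reports multiply by 100 for percentage tables). An empty mask scores
fitness 0 rather than raising, so the optimizer can traverse it. $d$ in
$\varphi(d)$ is the original pre-filter dimension, as the fitness is meant to
reflect the difficulty of the *original* problem; it is configurable.

## Evaluation pipeline

`run_pipeline()` wraps both stages in stratified outer cross-validation
(default 5 folds): per fold, the prefilter and the wrapper see the training
portion only; the selected mask and SVM parameters are then scored once on the
held-out fold. This is the leak-free protocol; a `refit_prefilter = FALSE`
compatibility flag fits the filter once on all data for comparison with
published setups that do not re-fit per fold. Reports store, per fold, the
kept dimension, the selected subset, validation CA, DR, and the weighted value
$\varphi(d)\,\mathrm{CA} + (1-\varphi(d))\,\mathrm{DR}$, plus their means —
all recomputable from the stored parts, which the tests assert. All stage
seeds derive from one master seed, so identical configurations give
byte-identical reports.

## What the synthetic generators emulate — and what they do not

`gen_feature_table()` plants known structure: *relevant* columns are
class-conditional Gaussians with a `class_gap` (default 2 SD) mean shift;
*redundant* columns are strictly monotone transforms (cube, scaled
exponential, asinh) of a relevant parent plus small noise, assigned
round-robin over parents; *irrelevant* columns are independent noise. The
planted guarantees are verified at generation with bounded redraws — redundant
columns reach pairwise MIC > 0.8 with their parent, irrelevant columns stay
below MIC 0.2 with the label, and relevant columns reach at least MIC 0.25
with the label (a margin above the irrelevance threshold, so the planted
ground truth is actually recoverable by the default filter at every seed).
Generation is a pure function of the spec and seed.

`gen_eeg_dataset()` emulates the acquisition design of a two-class
resting-state study: 58 subjects × 240 s at 256 Hz on 19 channels in 10-s
epochs (1392 epochs) by default. Each channel is a sum of five band-limited
sinusoids at 2/6/10/20/40 Hz with per-epoch random phases, 10% amplitude
jitter, and white noise; class 1 scales band amplitudes by `class_effect`
(default: alpha × 1.5, the kind of band-power group difference reported in
depression studies). This validates the *plumbing* — band mapping, feature
layout, class separability direction, chance-level behaviour under a null
effect — but it is deliberately not a biophysical EEG model: no 10–20 montage
geometry or volume conduction, no artifacts, no 1/f background, no
non-stationarity. Passing tests on this generator therefore demonstrate
correctness of the algorithms and their contracts, not clinical-grade
classification performance on real recordings.

## Problem sizes used by the test suite

The suite exercises the full stack at desk scale, chosen once as realistic
miniatures of the study conditions: planted tables of 300 samples × 20
columns (5 relevant / 3 redundant / 12 irrelevant, gap 2 SD); wrapper budgets
of $N = 30$, $T_{\max} = 60$ with 5 outer folds over 3 seeds for the
recovery checks; QPSO benchmark budgets of 30 × 200 (sphere) and 40 × 300
(Rastrigin); the layout checks run on 1-s epochs (the column count does not
depend on epoch length) while the epoch-count check generates the full
58-subject default once. In the recovery checks a planted relevant signal
counts as recovered when the selected mask contains its redundancy group's
surviving representative — the parent *or* one of its monotone clones — since
the filter deliberately keeps exactly one arbitrary member per group, and
which member survives depends on the training fold. Note also that the
dimension-aware fitness will happily trade a fifth informative feature for
the dimension-reduction bonus whenever the inner CV estimate does not drop,
so per-column recovery of *every* planted feature is not a property the
method claims.

## Known limitations

* MIC is the cost centre of the filter: the estimator is $O(\text{cells}^2)$
  per grid shape, and pairwise filtering over hundreds of surviving columns is
  quadratic in the number of accepted features. The greedy sweep already
  avoids the full pairwise matrix; very wide tables will still be slow.
* Absolute MIC values on noisy data differ slightly between estimators
  (superclump factor, tie policy); the thresholds 0.2 / 0.8 are conventions
  calibrated to this estimator family, not universal constants.
* Wrapper fitness is a cross-validated point estimate; with small inner folds
  the optimizer can exploit fold noise of a percent or two. The fixed inner
  fold seed makes this reproducible but does not remove it.
* The band↔level mapping is asserted for 256 Hz; other sampling rates shift
  the physical band edges proportionally and are accepted with that caveat.

## A worked miniature

```{r example, eval = FALSE}
tab <- gen_feature_table(seed = 1)          # 300 x 20, 5 relevant planted
rep <- run_pipeline(tab$features, outer_folds = 5,
                    n_particles = 30, t_max = 60, seed = 1)
print(rep)
```

On this table the pipeline keeps the five planted parents in the filter
(clones and noise columns removed), and the wrapper returns compact masks of
mostly planted-relevant features with held-out accuracy well above 0.9; the
acceptance tests pin those properties quantitatively.
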