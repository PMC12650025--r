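---
title: "Microstate and statistical feature fusion for EEG classification: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate and statistical feature fusion for EEG classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`microfuse` implements an end-to-end EEG classification pipeline built on
two feature families — microstate dynamics and per-channel statistical
descriptors — fused into one vector and classified by a parallel
convolutional/recurrent network trained under a validation-feedback loop.
This vignette is the package's account of the underlying models, the
parameters that matter, and the choices made where the design was open.

## The microstate model

Spontaneous EEG topographies do not drift continuously; they linger in one
of a small number of quasi-stable spatial configurations for tens of
milliseconds and then switch abruptly. The analysis pipeline estimates
this process in five steps:

1. **Global field power.** `GFP(t)` is the spatial standard deviation
   across channels at sample *t*. Local GFP maxima are moments of high
   signal-to-noise topographic expression, so template estimation uses
   only GFP-peak maps (`detect_gfp_peaks()`, default minimum peak
   separation 10 ms).
2. **Polarity-invariant clustering.** Peak maps are clustered by modified
   K-means (`cluster_templates()`): assignment maximises the *squared*
   spatial correlation — the generator of a topography is defined up to
   sign — and each template is the normalised sign-aligned mean of its
   members. Restarts (default 10) are scored by global explained
   variance. K = 4 by default, the canonical A–D decomposition.
3. **Two-level aggregation.** Per-subject templates are pooled and
   re-clustered into group templates (`two_level_cluster()`), the standard
   way to keep subject-level idiosyncrasy out of the group maps.
4. **Alignment.** Group templates are matched to reference maps by the
   assignment maximising total |spatial correlation| over all `K!`
   permutations (`align_to_reference()`; exhaustive, so provably optimal
   at K = 4), with signs flipped to positive correlation. The packaged
   reference maps (`canonical_templates()`) are *synthetic geometric
   approximations* of the canonical A–D topographies built from 10–20
   electrode coordinates — adequate to fix labelling order, documented as
   such, and user-replaceable.
5. **Backfitting and statistics.** Every sample is labelled with the
   template of maximal squared correlation (`backfit()`; ties take the
   lowest index). Runs of constant label yield mean duration, time
   coverage, and occurrence rate per state; transitions are counted at
   run boundaries, making the diagonal structurally zero and leaving 12
   off-diagonal probabilities; per-state GEV weighs squared correlation
   by GFP². Together: a 28-dimensional vector in fixed block order
   (duration 4, coverage 4, occurrence 4, transitions 12, GEV 4).

Counting transitions at run boundaries (rather than per sample) is a
documented choice: per-sample counting is dominated by self-transitions,
which the 12-probability formulation explicitly discards. "Temporal
statistics (12D)" is read as duration + coverage + occurrence; occurrence
rate is the field-standard third statistic alongside the two named ones.

**Label smoothing.** `backfit()` is unsmoothed by default, which keeps the
zero-noise synthesis→backfit round trip exactly identity. Under sensor
noise, isolated single-sample misassignments split runs and bias mean
durations downward; for duration-focused analyses we pass
`min_run_ms = 10` (one sample at 128 Hz), which merges only segments below
the physiologically meaningful timescale into their better-fitting
neighbour. Heavier smoothing is counterproductive: geometric run-length
distributions place real mass on 1–2-sample runs, and merging those
inflates durations (we observed the bias switching sign at ≥ 16 ms).

## The statistical feature block

`stat_features()` computes 40 descriptors per record (see
`stat_feature_names()`): moments and quantiles, RMS and peak-to-peak,
Hurst exponent, approximate/sample entropy, decorrelation time, five
relative band powers (δ θ α β γ) and four absolute band energies, Hjorth
mobility/complexity in both time and spectral forms, Higuchi and Katz
fractal dimensions, zero-crossing rate, line length, spectral slope/
entropy/95% edge frequency, SVD entropy and SVD Fisher information, and
six db4 wavelet detail energies. Features are computed per channel and
averaged across channels (configurable: `median`, `none`), because the
fused classifier input is a single short vector per record.

The inventory's expansion of multi-valued categories (3 quantiles, 5 band
powers, 4 band energies, 6 wavelet levels) into exactly 40 scalars is a
documented package convention — no printed enumeration exists to copy.

Parameter defaults follow field convention where the method itself does
not fix them: sample/approximate entropy at `m = 2`, `r = 0.2·SD`; SVD
embedding order 3, delay 1, retaining singular values above
`1e-12·σ_max`; Fisher information guard `ε = 1e-8`. The quadratic-cost
estimators (entropies, Hurst) run on the first 1024 samples of each
channel — their estimates stabilise well below full record length and the
cap keeps the per-record cost near one second. Sample entropy returns
`NaN` when no length-(m+1) template pair matches (a strictly monotone
series at tiny `r`); inside the feature table this is replaced by the
log of the maximal possible pair count, the conservative "maximally
irregular" reading.

`gini_select()` delegates the importance estimator to a random forest
(impurity-based importances, normalised to sum to one) and applies the
0.002 cutoff; the three information-theoretic features are exempt, since
the pipeline adds them deliberately after selection. Selection must be
fitted on training folds only — fitting it on all data leaks labels.

## Preprocessing

`preprocess()` runs band-pass → amplitude-artifact correction → average
reference. The band-pass is a zero-phase 4th-order Butterworth (0.5–45
Hz), covering δ through low-γ and excluding line noise. Artifact
correction is a sliding-window robust scheme in the spirit of artifact
subspace reconstruction's calibration logic: per channel, 0.5 s windows
(50% overlap) are summarised by RMS; windows exceeding
`median + k·(q₇₅ − q₂₅)` (default `k = 5`) are tapered down to that
envelope. The (0.25, 0.75) pair is interpreted as the quantiles defining
the robust spread — a (0.25, 0.75) threshold pair admits several readings
(quantiles, seconds, toolbox-specific cutoffs), and the quantile reading
matches the intended roles (a lower limit that aids artifact detection, an
upper limit that prevents over-correction) without reverse-engineering any
particular toolbox. ICA-based component cleaning requires
a trained component classifier and is out of scope; `preprocess()` exposes
a `component_hook` callback (default identity) where it would run.

## The classifier

The fused vector (28 + 40 = 68 dimensions with package defaults) enters
the network as a length-T sequence with one channel per step. Two branches
run in parallel:

* a convolutional branch — separable convolutions with kernels 3 and 5,
  batch normalisation, a residual 1×1 projection of the input added
  before the final ReLU, max pooling (width 2), flattening, dropout;
* a GRU branch — a standard gated recurrent unit (update/reset gates,
  candidate state, logistic/tanh nonlinearities, `h₀ = 0`) whose *last*
  hidden state is kept, with dropout.

The branch outputs are concatenated and passed through one dense ReLU
layer (dropout) to a single sigmoid unit. All forward and backward passes
are hand-written base R, and the backward pass is verified against central
finite differences in the test suite (worst relative error ~1e-7). The GRU recursion is sometimes written without bias terms, but the major
deep-learning frameworks carry them; we include one bias per gate,
matching the parameter-count convention `3·(D·U + U·U + U)`.

Hidden widths are package choices. Defaults — 32 and 64 convolution
filters, 64 GRU units, 64 dense units, dropout 0.5 — produce ~163k
trainable parameters at T = 71, a light model of the order of 10⁵
parameters. Architectures of this family are sometimes described with a
71-step input where the feature blocks described here total 28 + 40 = 68;
the fused dimension is therefore config-driven and never hard-coded.

## The feedback training loop

Each epoch ends with a validation pass producing accuracy and *unweighted*
cross-entropy (so rewards are comparable across loss weights — a
documented choice). The loop then applies, in order:

1. reward `R = val_acc − val_loss`;
2. loss-weight update `w ← clip(w + η·R, 0.5, 2.0)` (default `η = 0.1`);
3. stagnation check: no improvement over the running best by more than
   `ε = 0.001` for `T = 10` consecutive epochs triggers, alternately,
   a perturbation reset `w ~ U(0.7, 1.3)` and — if stagnation persists
   another `T` epochs — a resample of dropout ∈ {0.4, 0.5, 0.6, 0.7},
   learning rate ∈ {1e-3, 1e-4, 5e-5}, L2 ∈ {1e-3, 5e-4, 1e-4} with a
   full reinitialisation (fresh derived seed, fresh optimiser state —
   clean-restart semantics).

`η`, `ε` and `T` are free constants of the mechanism; the defaults above
are package choices, configurable and logged. The resampled dropout applies
to every dropout site, and a resampled learning rate replaces the
current one outright (it *is* the schedule). Training uses Adam at an
initial rate of 1e-4, batch size 64, a 500-epoch cap, and early stopping
with patience 40 on best validation accuracy; the patience counter resets
after a reinitialisation, because a reinitialised network is a new
trajectory. The returned model is the best-validation snapshot (ties
broken by lower validation loss). Training-set expansion is exactly 3N:
the originals, one Gaussian-noise copy (σ = 0.05 on the z-scored scale),
and one cutout copy (one contiguous 10% segment zeroed per vector),
never applied to validation or test data.

## Evaluation protocol

`make_subject_folds()` partitions *subjects* into stratified test folds;
the remaining subjects are split 80/20 into training and validation, again
at subject level, so no subject appears on both sides of any boundary.
Per fold the fusion normaliser (z-score, population SD, training rows
only) is fitted before augmentation; metrics are accuracy, precision,
recall, F1, Cohen's κ, and probability RMSE, aggregated as mean ± SD over
folds. Ratios with zero denominators are flagged `NA` rather than zeroed,
to avoid silently inflating averages. Group differences in microstate
features use the two-sided Wilcoxon rank-sum test with raw p-values at
α = 0.05 (the comparison the package mirrors reports raw significance);
a Benjamini–Hochberg option exists.

## The synthetic cohort generator

`generate_cohort()` inverts the microstate model: a semi-Markov sequence
(geometric run lengths — the maximum-entropy law consistent with a
first-order chain; successive states from a zero-diagonal row-stochastic
matrix) selects a template per sample, scaled by a rectified smoothed
Gaussian amplitude process (mean 1, ~50 ms smoothing) so GFP peaks exist,
plus additive noise. Defaults, chosen once as the package's study
conditions: 19 channels at 128 Hz; mean durations (80, 70, 90, 75) ms for
A–D, inside the 60–120 ms band the literature reports; uniform
off-diagonal transitions for controls. The case group encodes the
ADHD-like pattern — B duration ×1.5, C duration ×0.6, transition mass
shifted toward B and away from C in the A, B and D rows — so duration,
coverage and transition effects all point the way the group comparisons
the package mirrors report (B ↑, C ↓).

On the 19-channel montage the generating templates *are* the canonical
reference maps, so generator state identities and fitted (aligned) model
labels coincide — a prerequisite for comparing estimated features to
ground truth without a hidden permutation.

Noise has two parts, both scaled by `noise_sd` (default 0.05 relative to
the unit-norm templates, leaving topographic SNR high, as after
preprocessing): i.i.d. Gaussian sensor noise, and a narrowband
alpha-range background rhythm with per-subject random amplitude
(log-normal) and peak frequency (8.5–11.5 Hz), independent across
channels and demeaned across channels so the average-reference convention
survives. The background rhythm exists because real EEG statistics are
dominated by ongoing oscillations that carry no group information; without
it, the microstate switching rate of the two groups leaks losslessly into
spectral and complexity statistics, and a statistical-features-only
classifier matches the fused one — an artefact of over-clean synthesis,
not a property of the method. What the generator still does *not* emulate:
forward-modelled head geometry, 1/f spectral shape, artifacts, and
inter-channel noise correlation. Passing tests on this generator therefore
demonstrate correctness of the estimators and the training machinery under
known ground truth — not clinical performance on real recordings.

## Problem sizes and numerical choices

Test and acceptance runs use cohorts of 40 subjects (20 per group) with
60 s records; classification produces one fused vector per 15 s window
(windows inherit their subject, folds stay subject-disjoint, accuracy is
reported at window level), parameter recovery uses whole records, training
runs under a 150-epoch cap with patience 40 and an exploration budget of 4
reinitialisations, and evaluation is 5-fold subject-independent CV — sizes
at which every stage's statistical claims (recovery within 10%/±0.05,
CV accuracy of the fused stack ≥ 95%, ablation direction) are measurable
in minutes on one CPU. Windowed epoching matters for the deep classifier:
one vector per record leaves only ~25 training vectors per fold, too few
for a ~10⁵-parameter network even when an oracle linear classifier
separates the same features perfectly; 15 s windows quadruple the sample
count at modest per-window feature noise. For windowed runs the
quadratic-cost entropy estimators are capped at 512 samples per window. Convergence statistics for the simulator are
checked at 2×10⁵ samples against ±0.02 tolerances. Degenerate inputs are
defined, not accidental: flat records give GFP 0 and are rejected by GEV;
absent states carry zero duration/occurrence and an all-zero transition
row with a `present` flag; constant feature dimensions are dropped by the
normaliser with a warning; sample entropy without recurrences is flagged.
Ties break deterministically everywhere (first index in backfitting and
pooling, earlier peak on equal height, lower validation loss between
equal-accuracy snapshots).

## Known limitations

* The artifact-correction stage is a robust-envelope method *in the
  spirit of* subspace reconstruction, not a reimplementation of any
  specific toolbox; its (0.25, 0.75) reading is an assumption.
* The packaged reference maps are geometric idealisations; analyses
  aiming at canonical-class comparability on real data should substitute
  empirical grand-average templates.
* Single-record fitting skips the two-level step by construction.
* The epoch/segment length that yields one feature vector per training
  sample is not fixed by the method description; the package default is
  one vector per record, with windowing left to the caller.
* Network training in base R is practical at the package's design scale
  (inputs of ~10² steps, cohorts of ~10²
  subjects) but is not a GPU deep-learning stack.
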