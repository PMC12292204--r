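---
title: "Interpretable separable CNNs for task EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable separable CNNs for task EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cognitively healthy carriers of Alzheimer's-risk gene variants (APOE
ε4, with or without an additional PICALM risk allele) may show subtle
electrophysiological alterations during cognitive tasks long before any
symptom.  `eegsep` implements a complete pipeline for probing this:
trial-level classification of epoched task EEG (60 channels × 320
samples at 250 Hz, −80 to 1200 ms around stimulus onset) into
non-carriers (N) versus single-risk carriers (A+P−), with the dual-risk
group (A+P+) held out entirely and scored post hoc, plus a relevance
reconstruction that shows *where* on the scalp and *when* in the trial
the model found its evidence.

Because the comparable clinical recordings are not freely
redistributable, the package ships a synthetic cohort generator whose
defaults reproduce the study bookkeeping (21/18/12 subjects;
3176/2442, 2720/2151 and 1738/1364 trials per group under the MSIT and
STMT task conditions).  Every empirical claim in the test suite is made
against this generator.

## The network

The classifier is a seven-layer separable convolutional network that
maps a raw epoch $X \in \mathbb{R}^{C \times T}$ (µV; no input
normalization — batch normalization handles scale) to two class
probabilities:

1. **Pointwise (spatial) convolution.**  $S = 16$ rows of a weight
   matrix $W \in \mathbb{R}^{S\times C}$ demix the montage at each time
   point: $d_s(t) = \sum_c W_{sc} X_c(t) + b_s$.  Each row is a learned
   spatial filter ("virtual source").
2. **Depthwise (temporal) convolution.**  $D = 2$ kernels of length
   $L = 64$ slide over each demixed source independently (valid
   padding, stride 1), giving $S\cdot D = 32$ feature maps of length
   $T - L + 1 = 257$.  The grouping is *true* depthwise grouping
   (one group per source).  The published layer table prints a group
   count of 2 for this layer, but the accompanying description —
   learning temporal features from each demixed signal independently —
   requires one group per source, and the relevance reconstruction
   below relies on that independence; we therefore implement
   groups = S.
3. **ReLU**, then **batch normalization** (in that order, following the
   published layer sequence), **global average pooling** over time, a
   **dense** read-out to 2 logits, and **log-softmax**.

Softmax plus negative log-likelihood is implemented as log-softmax
feeding the NLL objective — numerically stable and mathematically
identical.  Initialization is uniform fan-in scaling
($U(-1/\sqrt{f}, 1/\sqrt{f})$), biases zero, fully seed-controlled; the
source publication is silent on initialization, and this is the
conventional choice.  Batch-norm eps is $10^{-5}$ and momentum 0.1
(conventional defaults, exposed in `model_config()`).  Bias terms: on
the pointwise stage, none on the depthwise stage (also exposed; the
original is unstated).

The forward and backward passes are written in R with the two
depthwise convolution kernels in C++; gradients are verified against
numerical differentiation in the test suite.

## Training

`eegcnn()` optimizes the mean NLL with Adam (lr 0.001, β = 0.9/0.999,
batch size 64) for at most 200 epochs, evaluating validation binary
accuracy (argmax, evaluation-mode batch statistics) after every epoch.
Early stopping: "improvement" means *strictly* exceeding the best
accuracy so far — ties do not reset the patience counter (otherwise an
accuracy plateau would count as endless progress) — and training halts
after 20 consecutive non-improving epochs, returning the weights of the
best epoch.  With `patience = 0` training stops at the first
non-improving epoch.

Two documented deviations from pure protocol semantics are available:

* `restore_best = FALSE` keeps the final weights.  On easily separable
  synthetic cohorts validation accuracy saturates within one or two
  epochs while the spatial filters are still essentially random; the
  interpretability experiments therefore train to convergence rather
  than stopping at the (instantly reached) accuracy optimum.
* The validation set that drives early stopping is the same held-out
  subject set used for the fold metrics; the resulting optimism is a
  property of the emulated protocol, which describes a single
  validation set, and is noted here rather than silently "fixed".

No class reweighting is applied.

## The leave-p%-subjects-out protocol

`run_lpso_cv()` runs 100 iterations seeded 42–141 (both the count and
the range are part of the emulated design).  Each iteration holds out a
stratified fraction p of *subjects* per training group — never trials —
so no individual contributes to both sides.  p defaults to 0.20: the
source defers the exact value to prior work, and 0.20 keeps at least
three held-out subjects per group at the default cohort sizes; it is a
flag, not a constant.  Each iteration's seed spawns three independent
sub-seeds (split, weight initialization, batch shuffling).  After each
iteration the trained model scores every trial of the held-out A+P+
group; the fraction assigned to the risk class is that group's
sensitivity.  The `ALL` condition pools MSIT and STMT trials of the
same subjects under the same split, mirroring the three-column results
layout.  A fold whose validation set degenerates to a single class is
flagged invalid, recorded, and excluded from summaries — never silently
dropped.

Metrics are self-contained and oracle-tested: rank-based ROC AUC
(ties one half; equal to the pairwise Mann–Whitney probability), Cohen's
kappa from argmax predictions ($p_e = 1$ degenerates to 0 with a
warning), and sensitivity.  The published results table reports kappa
values exactly equal to 2·AUC − 1 in every column, suggesting a kappa
derived from AUC; this package computes standard Cohen's kappa from the
confusion matrix, and the two will generally differ.  Landis–Koch
agreement bands round kappa half-up to two decimals and use left-closed
intervals (0.21–0.40 = "fair"), matching the published usage of
0.22 → fair.

## Relevance reconstruction

The interpretability method is a class-activation-map-style
reconstruction fixed as follows (the cited CAM formulation lives in an
external reference; this is the normative algorithm of this package):

1. temporal relevance of feature map $m$ for target class $k$:
   $r_m(t') = w_{km}\,\mathrm{relu}(a_m(t'))$ with $a_m$ the post-batch-
   norm activation ($w$ = dense weights).  Pre-batch-norm activations
   are available behind `activations = "pre_bn"`;
2. source relevance: sum over each source's D maps, linearly upsampled
   from length 257 to 320 (the simplest monotone scheme);
3. spatial redistribution: source s's relevance is spread over input
   channels proportionally to $|W_{sc}|$;
4. negative mass is clipped (the emulated figures display excitatory
   evidence only) and the map normalized to sum 1.

A map with no positive evidence (e.g. a zero read-out row) falls back
to the uniform map — the documented degenerate contract.
`localization_score()` is the total mass on a channel set (uniform
baseline: set size / 60); `region_relevance()` normalizes per channel so
regions of different sizes compare fairly, and its argmax is the
"where did the model look" summary used by the recovery experiment.
`band_power()` (detrended, Hann-tapered periodogram mass over
half-open bands delta 1–4, theta 4–8, alpha 8–13, beta 13–30 Hz —
conventional clinical edges; the source never prints its own) and
`topographic_grid()` (inverse-distance-weighted interpolation on the
unit disc) reproduce the band-topography views.

## The synthetic cohort generator

`generate_cohort()` emulates exactly the statistical structure the
analysis assumes, and nothing more:

* **1/f background**: frequency-domain-shaped Gaussian noise with
  spectral slope 1 and per-channel SD 10 µV (plausible EEG magnitude).
* **Class signatures**: random-phase sinusoids with frequency uniform
  in the band per trial, spatially coherent over the target region.
  Defaults: risk groups carry theta (4 µV) and alpha (3 µV) over the
  parietal + temporal regions; non-carriers carry frontal alpha (3 µV);
  the dual-risk group carries the *same* bands and regions at 0.75×
  amplitude — similar to, yet different from, the single-risk group, so
  post hoc generalization is meaningful.  Effect sizes are calibration
  knobs, not estimates: the source quantifies none.
* **Hierarchy**: a per-subject Gaussian amplitude offset (SD 1 µV,
  truncated at zero) then per-trial jitter (SD 0.5 µV).  This is what
  makes subject-wise splits genuinely different from trial-wise splits.
* **Artifacts**: ocular — a slow Gaussian-windowed transient (σ = 120 ms,
  spectral content below 4 Hz) on frontal channels with weights decaying
  from the anterior pole; EMG — a Hann-windowed burst of >20 Hz
  sinusoids on temporal channels.  Default rate 5% of trials each,
  identical across groups (artifacts are noise, not signal).
* **Bookkeeping**: scaled group trial totals are allocated exactly
  (floor + remainder), so the generated counts always match the
  specification, including the full-scale totals of 5618/4871/3102.

Not simulated: raw continuous recordings, filtering/ICA preprocessing,
event-related-potential morphology, realistic volume conduction,
age/sex covariates (unused by any computation).  Passing tests
therefore demonstrate that the *pipeline* recovers what was planted
under the stated noise model — not that real preclinical EEG carries
recoverable risk signatures.

## Desk-scale experiment sizes

The validation experiments run the full pipeline at sizes a laptop
handles comfortably; all sizes are package choices, stated here:

* *Planted-signal recovery*: default cohort at `scale = 0.075`
  (≈20 trials/subject over both tasks), risk theta amplitude 12 µV —
  about three times the in-band 1/f background RMS (≈3.8 µV in theta) —
  10 CV iterations, training capped at 15 epochs (patience 4).
  Expected: mean validation AUC ≥ 0.90.
* *Null calibration*: identical but all amplitudes zero; the groups are
  then exchangeable and mean AUC must sit near 0.5.
* *Localization recovery*: 20 runs cycling a 12 µV theta signature
  through frontal/parietal/temporal in a small two-group cohort
  (8 + 8 subjects, 12 trials each), trained to convergence (40 epochs,
  final weights).  Expected: mean localization gain over the uniform
  baseline ≥ 0.1 and the argmax region correct in ≥ 80% of runs.
* *Generalization direction*: a 10/10/6-subject cohort with 8 µV risk
  signatures and the 0.75× shifted third group, 20 CV iterations.
  Expected: mean test-group sensitivity ≤ mean validation sensitivity.

## Numerical choices and degenerate inputs

* Valid convolution requires `n_samples > temporal_kernel_len`
  (enforced at configuration time).
* Batch-norm uses biased variance for normalization and unbiased for
  the running estimate, the convention of mainstream frameworks.
* All randomness flows through explicitly derived sub-seeds
  (multiplicative congruential mixing, modulus $2^{31}-1$); library
  calls never disturb the caller's RNG state.
* Ties in argmax predictions resolve to the first (negative) class;
  ROC AUC handles score ties by half-counting.
* A periodogram Parseval identity (band masses plus out-of-band mass
  equal the signal variance) holds to a few percent on flat spectra;
  on steep 1/f spectra linear detrending removes genuine sub-band
  mass, so the strict check is made on white noise.
* Zero-trial cohorts keep their subject table; zero-amplitude
  signatures and zero-amplitude artifacts are exact identities.

## Limitations

The generator's sinusoidal signatures are far more stereotyped than
real oscillatory bursts; volume conduction, inter-channel correlation
of the background, and non-stationary artifacts are absent.  The
relevance reconstruction is one fixed member of the CAM family; it
uses only quantities the architecture exposes and is validated by
planted-signal recovery, not by biological ground truth.  Headline
numbers from the emulated study (AUC ≈ 0.61, kappa ≈ 0.22 on clinical
recordings) are properties of data this package cannot access and are
deliberately not reproduction targets.
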