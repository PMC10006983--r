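---
title: "Identifying people from their SSVEPs: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying people from their SSVEPs: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepid)
```

## The problem

When a person looks at a light flickering at frequency $f$, occipital EEG
shows a steady-state visual evoked potential (SSVEP): a narrowband response at
$f$ and its harmonics. How that response projects onto the scalp depends on
the anatomy and functional organization of the individual's visual cortex, so
the *spatial pattern* of the response — not just its strength — carries
identity information. `ssvepid` turns that observation into a biometric
identification pipeline:

1. **Temporal filtering.** Each trial $X \in \mathbb{R}^{N_{ch} \times N_t}$
   is band-passed through a filterbank of $B$ zero-phase Butterworth filters,
   giving $X^{(b)}$, $b = 1, \dots, B$.
2. **Spatial filtering (FBCSP, one-vs-rest).** For each person $i$ and band
   $b$, common-spatial-pattern filters maximize the variance ratio
   $J(w) = \frac{w^\top C_1^{(b)} w}{w^\top C_2^{(b)} w}$, where $C_1^{(b)}$
   is the mean trace-normalized covariance of person $i$'s band-$b$ trials and
   $C_2^{(b)}$ that of everyone else's. Stationary points solve the
   generalized eigenproblem $C_1 w = \lambda C_2 w$; the $p$ eigenvectors from
   each end of the spectrum form $W^{(b)} \in \mathbb{R}^{N_{ch} \times 2p}$,
   normalized so $w^\top C_2 w = 1$.
3. **Log-variance features.** $Z = (X^{(b)})^\top W^{(b)}$, and
   $f_j = \log \operatorname{var}(Z_{\cdot j})$ with the population ($1/N_t$)
   variance. Concatenation over persons, bands and filters gives a feature
   vector of length $I = N_p \cdot B \cdot 2p$.
4. **Classification.** A deep feedforward network of up to three
   FC + batch-norm + ReLU blocks with widths $(D_1, D_2, D_3) = (500, 100, 50)$
   — expand first ($D_1 \gg I$), then contract ($D_3 > C$) — and a softmax
   head, trained with Adam on the cross-entropy; the epoch snapshot with
   lowest validation loss is kept. A linear one-vs-rest SVM and a kNN share
   the same features as comparators.
5. **Evaluation.** Leave-one-block-out (LOBO) cross-validation per
   stimulation frequency; correct recognition rate (CRR, the mean diagonal of
   the row-normalized confusion matrix, in percent); and the usability
   measure $U = \frac{N \cdot \mathrm{CRR}}{T_r + K \cdot T_e}$, which
   discounts accuracy by training duration $T_r$, electrode count $K$ and
   test duration $T_e$.

## What the synthetic generator emulates

Real SSVEP benchmarks are multi-gigabyte downloads, so the package carries a
generative model sufficient to exercise every pipeline stage:

* **Sources.** Each subject has `n_sources` cortical sources replaying the
  stimulation frequency and its harmonics with amplitudes $(1, 0.5, 0.25)$ —
  a typical SSVEP harmonic roll-off (the number of harmonics and their decay
  are artifact-level choices; nothing in the identification method depends on
  them). Additional sources reuse the harmonic series in phase quadrature so
  their time courses stay linearly independent.
* **Identity.** A subject-specific mixing matrix $A$ (unit-norm random
  columns) maps sources to channels: $X = A S + \text{noise}$. The
  `subject_separation` knob spherically interpolates every subject's columns
  toward one shared base matrix; at 1 all subjects are identical and any
  classifier must fall to chance, which the tests verify.
* **Noise.** White, or an equal-power mix of white and $1/f$-shaped noise
  (the default, because raw EEG is dominated by its $1/f$ background), scaled
  so the aggregate channel signal-to-noise power ratio equals `snr_db`
  exactly.
* **Determinism.** Random streams are split per (subject, block, frequency)
  cell, so the data set is a pure function of its configuration and adding
  blocks never changes existing trials.

What it deliberately does **not** model: volume-conduction head geometry,
eye-blink/EMG artifacts, inter-session electrode-placement drift,
non-stationarity over time, or phase-coded stimulation. Passing tests on this
generator therefore demonstrate that the pipeline recovers identity *when
identity is encoded as a stable spatial mixing pattern* — the method's working
premise — not that any particular real-data accuracy will be reached.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| Filter family / order | Butterworth, order 4, forward–backward | Maximally flat passband; the two-pass application cancels phase and doubles the effective order. Edge transients are tamed with odd-reflection padding of $3(\text{order}+1)$ samples. |
| Filterbank | 8–30 Hz in 4 equal bands | An equal partition of the analysis range is the least arbitrary default; fully configurable (`filter_bank()`). |
| Filter/window order | filter, then window | Short analysis windows must not inherit filter edge effects, so trials are filtered full-length and then cut to TW. |
| $p$ | 2 | 4 filters per one-vs-rest problem; the established FBCSP convention of 2–3 per spectrum end. |
| Diagonal loading $\gamma$ | $10^{-6}$ | $C \leftarrow (1-\gamma) C + \gamma \frac{\mathrm{tr}(C)}{N_{ch}} I$ guards invertibility of the rest covariance; raised (with a warning) when its condition number exceeds $10^{10}$. |
| Hidden widths | (500, 100, 50) | The expand-then-contract schedule, checked at build time ($D_1 > I$, decreasing, $D_3 > C$). |
| Learning rate / batch / epochs | 0.001 / 32 / 200 | Adam defaults with a hard epoch cap; no early stopping beyond lowest-validation-loss snapshotting. |
| Validation split | stratified 20% by subject | Guarantees every identity appears in validation; a `"one-block"` mode holds out a whole block when enough blocks exist. |
| Feature standardization | z-score with training statistics | Applied before the network **and** the distance-based comparators alike, keeping the comparison fair; batch-norm alone would not protect SVM/kNN. |
| $T_r$ in $U$ | 25 s | Five training blocks × 5 s trials under six-block LOBO; exposed as a parameter because some protocols imply other training durations. |

Numerical conventions worth knowing: variances are population ($1/N_t$),
logs natural, projected variances below $10^{-12}$ are clamped before the
log (and flagged), eigenvector signs are fixed by making each column's
largest-magnitude entry positive, and exact eigenvalue ties are ordered by
that entry's row index — so fitted models are byte-comparable across runs.

## Design choices that were genuinely open

* **Multiclass SVM.** The comparator is specified as a *one-vs-rest* linear
  SVM; the underlying libsvm binary solver is wrapped per class and the
  decision-value orientation is normalized empirically at fit time, because
  libsvm's sign convention follows label encounter order.
* **kNN tie-breaking.** Ties are resolved by the smallest mean distance among
  tied classes, then the lowest class index — declared, so predictions are
  reproducible rather than dependent on storage order.
* **Covariance averaging.** Per-trial trace normalization *then* averaging
  (the common convention); the alternative order is nearly indistinguishable
  at realistic trial counts.
* **Enrollment artifacts.** Enrollment persists exactly three artifacts —
  spatial filters, feature store (with the standardizer), and the trained
  network — plus a manifest carrying the full canonical configuration rather
  than a hash, so reruns are verifiable byte-for-byte.

## Problem sizes in the test suite

The shipped tests run a scaled-down but complete study: the standard
benchmark is 10 subjects × 6 blocks × one 10 Hz stimulus, 9 channels at
250 Hz, 5 s trials, 10 dB SNR, fully separated mixing matrices. At these
conditions the full FBCSP + network pipeline reaches 100% LOBO CRR (and must
stay ≥ 90% to pass), the comparators are not better on the mean over five
seeds, and with identical mixing matrices the CRR falls inside the binomial
chance band around 10%.

Two direction-only trend checks mirror the published pattern of results.
The window-length sweep (TW ∈ {0.5, 1, 2.5, 5} s) runs at −10 dB SNR: at the
benchmark's 10 dB the CRR saturates at 100% for *every* TW, leaving a rank
correlation over a constant profile undefined, while at −10 dB covariance
estimation is duration-limited and the monotone CRR-vs-TW trend is
measurable. The ablation comparison (full three-block network vs. the
single-B3 variant) runs at 0 dB and TW = 0.5 s over ten seeds and requires
that depth does not hurt the mean CRR. At these conditions both variants sit
at ceiling on this generator (≈ 99.9%), so the comparison resolves to
single-trial sampling noise: a one-misclassification difference over the 600
pooled test trials moves the mean by 0.17 points and can flip its sign. The
check is kept strict rather than padded with a noise allowance, which means
it can fail at ceiling even though depth demonstrably does not hurt; the
regime where depth genuinely matters on real recordings (accuracy far from
ceiling at short windows) is not reachable by this generator at 0 dB.

## Known limitations

* The generator's identity signal is stationary and noise-free in structure;
  real EEG biometrics degrade across sessions and months, which this package
  does not model or measure.
* Reproducing the published real-data tables requires downloading the public
  Speller/EPOC benchmarks; an optional, clearly-separated script documents
  that protocol (`inst/scripts/speller_benchmark.R`) but is not part of the
  test surface, and stochastic network training means table values are only
  expected within a few CRR points.
* ANOVA/post-hoc utilities are reporting tools; the post-hoc procedure
  (pairwise Welch t-tests, Bonferroni) is one reasonable reading of an
  underspecified convention, and is labelled as such.
* Only identification (closed-set, one-of-N) is implemented — no
  verification/authentication metrics such as FAR/FRR or EER.
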