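---
title: "Decoding movement intention from EEG-EMG connectivity networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding movement intention from EEG-EMG connectivity networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurofuse)
```

## The decoding problem

A person preparing to stand up or sit down shows characteristic changes in
cortical and muscular activity *before* the movement begins. `neurofuse`
classifies 1.5-s pre-movement windows of simultaneous EEG (22 scalp
channels, 1 kHz) and EMG (6 thigh-muscle channels, 1.5 kHz) into
sit-to-stand, stand-to-sit, or rest. The classified object is not the raw
time series but the **functional-connectivity network**: a symmetric
adjacency matrix whose entries measure the statistical dependence between
every pair of channels in the window. The working assumption is that the
*topology* of corticomuscular coupling — which channel pairs are
co-active — differs between movement preparations, whereas overall signal
amplitude is an unreliable cue (it drifts with electrode impedance,
fatigue, and effort).

## From signals to networks

**Preprocessing.** EEG is band-pass filtered 0.5–45 Hz and re-referenced to
the common average; EMG is band-passed 15–300 Hz with a 48–52 Hz notch. All
filters are Butterworth designs (order 4 by default) applied forward and
backward for zero phase. Two numerical choices matter here:

- Filtering runs as a cascade of second-order sections rather than one
  expanded transfer function. With a 0.5 Hz edge at a 1 kHz rate the poles
  sit within 1e-3 of the unit circle, and the expanded polynomial form
  loses several digits; biquads keep the forward/backward passes consistent
  to better than 1e-6 relative.
- Edge transients are suppressed by odd-reflection padding of
  `3 * order * rate / f_char` samples (capped at signal length − 1), where
  `f_char` is the low cutoff for a band-pass and the stop-band *width* for
  a notch — a 4 Hz-wide notch rings for roughly `rate/4` samples, far
  longer than its center period.

**Movement onset.** The Teager–Kaiser energy operator
`psi[n] = x[n]^2 - x[n-1] x[n+1]` amplifies the abrupt
amplitude-and-frequency change at EMG burst onset. The threshold is
`T = mu + h sigma` with `h = 5`, where `mu`, `sigma` are taken from a
baseline window 3 to 2 s before the visual cue; the onset is the first
sample of the first run of strictly more than `run_len = 20` consecutive
supra-threshold samples (a run of exactly 20 does not qualify), searching
forward from the cue so that baseline artifacts cannot trigger. Raw
sample-wise TKEO of a stochastic burst is heavy-tailed — individual samples
of a strong burst still dip below any fixed threshold often enough that
20-sample uninterrupted runs are unreliable — so a 10 ms centered moving
average (`smooth_s = 0.01`) is applied before thresholding. This is the
standard conditioning step for TKEO onset detectors; it delays or advances
the detected onset by at most half the smoothing window, well inside the
30 ms recovery tolerance used in the tests.

**Windows.** Epochs are half-open sample intervals
`[onset + round(start*rate), onset + round(end*rate))`, so adjacent windows
never double-count a sample. The default intention window is [−1.5, 0) s
relative to movement onset and the rest window [−4, −2.5) s, inside 6-s
trials spanning [−4, 2) s. EMG is resampled (rational-factor polyphase,
anti-aliased) from 1.5 kHz down to the 1 kHz EEG clock before any
cross-modal computation — downsampling the higher-rate signal avoids
interpolating EEG, and thigh-EMG content above 500 Hz is negligible after
the 15–300 Hz band-pass.

**Edge estimators.** Three estimators are provided:

| method | definition | band | notes |
|---|---|---|---|
| `coh` | magnitude-squared coherence via Welch cross/auto-spectra | mean over 13–30 Hz, edges inclusive | Hann window, 1 s segments, 50% overlap |
| `cc`  | Pearson correlation | broadband | signed `r` is kept |
| `mi`  | histogram plug-in mutual information (bits) | broadband | 16 equal-width bins per series over its own range |

The MI bin count is a bias/variance compromise for 1500-sample windows: the
plug-in bias is roughly `(B-1)^2 / (2 n ln 2)` bits (about 0.11 bits at
`B = 16`, `n = 1500`), constant across edges of the same length and
therefore harmless to the *relative* network structure that the classifier
uses. A 1.5-s window yields only two 1-s Welch segments, which is why the
coherence weighting is noisy at this window length — the package reproduces
the finding that MI is the strongest weighting, and coherence the weakest,
without any estimator-specific tuning.

Each trial's adjacency matrix has a zero diagonal (self-connectivity is
constant and uninformative) and is min–max standardized over its own
off-diagonal entries onto [0, 1]. Standardization is per matrix, not per
dataset, so no test-trial statistic ever reaches training. A window whose
off-diagonal weights are all equal is degenerate and rejected with an
error. Signed correlations enter standardization as `r`, not `|r|`: the
affine map carries the signed range into [0, 1] monotonically.

## Discriminative spatial network filters

For a class pair (i, j), with standardized matrices `M` of class i, the
scatter is `C_i = (1/N_i) sum M M'` (no trace normalization — unlike
classical CSP on covariance matrices, the networks are already on a common
[0, 1] scale). A spatial filter `w` maximizing
`J(w) = (w' C_i w)/(w' C_j w)` solves the generalized eigenproblem
`C_i w = lambda C_j w`. The package solves it in whitened coordinates:
eigendecompose `C_j = V D V'`, form `P = V D^{-1/2} V'`, and take the
symmetric eigendecomposition of `P C_i P`. This is numerically symmetric,
and back-transformed eigenvectors satisfy the non-symmetric form
`C_j^{-1} C_i W = W Lambda` exactly.

Numerical choices:

- **Regularization.** `C_j` gets a ridge `gamma * tr(C_j)/n * I`
  (`gamma = 1e-6`) *only* when numerically rank-deficient (minimum
  eigenvalue below 1e-10 of the maximum), which happens when a class has
  fewer trials than channels. Well-conditioned problems are solved exactly,
  keeping the eigen-equation residual below 1e-6 relative.
- **Normalization.** Each returned filter is rescaled so `w' C_j w = 1`,
  the constraint under which the Rayleigh problem is posed; features are
  then comparable across filters.
- **Sign.** The largest-magnitude entry of each filter is made positive, so
  outputs are reproducible across linear-algebra backends.
- **Selection.** The eigenvectors of the 2 largest and 2 smallest
  eigenvalues are kept: large lambda directions maximize class-i energy
  relative to class j, small-lambda directions the reverse.

**Features.** The original description of the multiclass procedure does not
state the post-projection feature functional. The package uses
`f_k = log(w_k' M M' w_k + 1e-12)`, the log-projected network energy,
mirroring the log-variance convention of spatial-pattern decoders: the
quadratic form is the natural invariant of the Rayleigh problem, and the
log both symmetrizes its skewed distribution and turns the global scale of
`M` into an additive constant that the subsequent z-normalization removes.

## Classification and validation

One linear SVM (cost 1, features z-normalized with training statistics) is
trained per class pair — `c(c-1)/2 = 3` units for three classes. A test
network is projected through each pair's filters; each unit votes and the
majority wins. Because three pairwise units can tie cyclically, ties are
broken by the largest summed absolute SVM decision margin over each class's
votes, then deterministically by class order. The SVM decision-value sign
convention is calibrated against training-class means at fit time rather
than assumed from the backend.

Cross-validation is stratified k-fold (default 10) with a recorded seed;
the *entire* pipeline from class scatter and filter learning onward is
refit inside each training fold. This is the only leakage-free reading of
the procedure, and the package's label-permutation control verifies it:
with permuted labels, cross-validated accuracy collapses into the chance
band. Accuracy is compared against the binomial chance level
`T = 100/n * min{ m : F(m; n, 1/c) >= 1 - alpha }`, computed by the exact
binomial quantile — 39.375% at `alpha = 0.05`, `n = 160`, `c = 3`.

With 40 trials of each of sit-to-stand and stand-to-sit per session and
rest windows available from both transitions of a trial, a session supports
up to 4 epochs per trial (n = 160); balanced three-class designs (equal
trials per class) are what the cross-validation pipeline consumes, and the
synthetic studies below use 40 trials per class.

## Muscle-fatigue indices

The mean and median frequency of the EMG power spectrum,

- `MNF = sum(f_i P_i) / sum(P_i)`,
- `MDF`: the frequency splitting cumulative power into halves,

both shift downward as a muscle fatigues. Spectra come from Welch
estimation (Hann, 1 s segments, 50% overlap). On a discrete grid the exact
two-sided MDF equality is generally unattainable, so the package returns
the first bin where cumulative power reaches half the total — the standard
discrete convention; the difference from any interpolated convention is at
most one bin (1 Hz at the default resolution). `fatigue_trend()` slides a
window (default 5 s, 2.5 s step) along a recording and fits an ordinary
least-squares line to each index against window midpoint time; persistent
negative slopes are the fatigue signature.

## What the synthetic generator does and does not emulate

`generate_epochs()` plants class structure exactly where the decoder looks
for it: each channel is band-limited background noise (EEG: pink, 0.5–45 Hz
at 1 kHz; EMG: flat, 15–300 Hz at 1.5 kHz), and each class owns a list of
channel pairs into which a shared beta-band (13–30 Hz) latent source is
mixed with weight `coupling_strength * noise_sd` (default 0.8). A single
latent drawn on a common 3 kHz grid and subsampled to each endpoint's rate
elevates coherence, correlation, and mutual information on the planted edge
simultaneously. The rest class has no planted coupling. Classes differ
*only* in which edges are coupled — the topology premise of the method —
and EEG/EMG are generated at their native rates so the resampling path is
always exercised. `fusion_favorable_edges()` provides a layout where each
single modality carries only partial class information, for studying the
value of fusion. `generate_emg_trial()` produces baseline EMG with a
planted 10x burst after the cue for onset-detector studies, and
`spectral_compression_series()` a noise series whose spectral center drifts
linearly downward as a fatigue surrogate.

The generator is deliberately minimal. It does not emulate volume
conduction, electrode artifacts, eye or heart contamination, trial-to-trial
amplitude drift, nonstationary coupling within a window, or biophysical
motor-unit structure. Passing the recovery studies therefore shows that the
estimators, filters, and ensemble recover planted network topology under
realistic rates, dimensions, and noise — not that the method overcomes
every pathology of real scalp recordings. Artifact removal (ICA-based or
otherwise) is expected to happen upstream; the readers accept pre-cleaned
signals.

## Study conditions used by the tests and acceptance script

All simulation sizes are package choices, fixed before the studies were
run: the main recovery study uses the generator defaults (40 trials/class,
coupling 0.8, seed 7; 10-fold CV), the fusion-vs-unimodal sweep 30
trials/class over 20 seeds, the permutation control 5 label permutations,
and the onset studies 100 seeded trials per condition. The
generalized-eigenvalue solver is checked against a brute-force Rayleigh
maximization on a 1-degree unit-sphere grid (3x3 problems, 50 pairs), the
MI estimator against an explicit double-loop histogram oracle and the
plug-in bias bound, and the chance level against exhaustive binomial-CDF
summation for all n up to 500.

## Known limitations

- Coherence from 1.5-s windows rests on two Welch segments and is
  correspondingly noisy; it is retained for comparability, not recommended.
- The MI estimator is the equal-width histogram plug-in; k-NN estimators
  would have lower bias at these window lengths but a data-dependent
  geometry that standardization could distort.
- Only unordered, undirected connectivity is implemented — no lagged or
  directed measures (Granger, transfer entropy), and no source-space
  analysis.
- The pairwise ensemble scales as c(c-1)/2; it is designed and tested for
  the three intention classes only.
- EDF/BDF ingestion is not built in; recordings enter via delimited text,
  the RDS container, or in-memory construction.
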