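---
title: "ECG identification with eigen-filter banks: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ECG identification with eigen-filter banks: models, parameters, design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(eecgnet)
```

## The problem and the model

ECG biometrics rests on the observation that the averaged heartbeat
waveform is stable within a person and discriminative between people. The
pipeline in this package has three parts.

**1. Beat extraction.** Each record is reduced to one averaged beat per
lead: a wide moving average (default 500 samples) estimates and removes
baseline wander; a short moving average (default 10 samples) suppresses
high-frequency noise and single-sample spikes; R peaks are detected as
local maxima above half the global maximum, thinned greedily with a 0.3 s
refractory window (the larger peak wins; on exact ties the earlier index);
400-sample windows centered on the usable peaks are averaged. Averaging
`n` beats attenuates zero-mean noise by about `sqrt(n)`, which the test
suite verifies directly. The per-lead averages are concatenated, linearly
resampled to the target length `m * n`, normalized to zero mean and unit
maximum absolute value, and reshaped row-major into an `m x n` image.

**2. Eigen-filter banks.** All `k1 x k2` patches of the training images
(zero-padded so every pixel contributes a patch) are vectorized
column-major and mean-removed per patch. The stage-1 kernels are the top
`L1` eigenvectors of the pooled patch scatter matrix, reshaped back to
`k1 x k2`; this is the rank-`L1` solution of the patch reconstruction
problem, so the kernels capture the dominant local waveform geometry.
Every image is convolved with every kernel (true convolution, zero-padded
to the input size), and stage 2 repeats the eigen-analysis on the pooled
patches of all `N * L1` maps, yielding one shared bank of `L2` kernels
applied to every channel.

**3. Hashing and histograms.** Per stage-1 channel, the `L2` stage-2 maps
are binarized with the Heaviside step (1 for strictly positive values)
and combined with weights `2^(l-1)` into a single integer-coded image with
values in `0 .. 2^L2 - 1`. Overlapping `h1 x h2` blocks (stride
`round((1 - R) * h)`) are summarized by `2^L2`-bin count histograms,
concatenated over blocks and channels. The feature length is
`2^L2 * L1 * B` and every image's feature sums to `L1 * B * h1 * h2` — a
conservation law the tests assert for every transformed image. A
multi-class linear SVM classifies the features; with `10^5`-dimensional
sparse count vectors a nonlinear kernel adds nothing.

## Parameters that matter

| Parameter | Meaning | Default | Rationale |
|---|---|---|---|
| `m, n` | beat image size | 28, 28 (single-lead) | 784-sample beat vector; 40 x 40 for two-lead records |
| `k1, k2` | patch/kernel size (odd) | 7 | beats are smooth; mid-sized patches span one deflection |
| `L1, L2` | kernels per stage | 8 | filter counts between 4 and 8 work well; `L` near `k^2` degrades (tested as an ordering on synthetic cohorts) |
| `h1, h2` | histogram block | 7 | local enough to keep spatial information |
| `R` | block overlap ratio | 0.5 | moderate overlap; block count grows with `R` |
| `width` (baseline) | baseline window | 500 samples | about one beat at 500 Hz |
| `width` (smooth) | smoothing window | 10 samples | kills spikes, keeps QRS |
| `window` | beat window | 400 samples | covers P-QRST at 360–500 Hz |
| `refractory` | min peak spacing | 0.3 s | below any physiological RR |
| `C` | SVM cost | 1.0 | features are counts on a common scale |

## The synthetic generator

Each subject is a template of five Gaussian deflections (P, Q, R, S, T)
with amplitudes, widths, centers and mean RR drawn uniformly from fixed
physiological-looking ranges; the R wave is pinned positive and largest so
peak detection is well posed. Records add sinusoidal baseline wander,
white noise, and sparse random-sign spikes; beat-to-beat RR jitter is
Gaussian. A second lead, when requested, is the clean beat train scaled by
0.6 with P and T sign-flipped plus independent noise — a fixed linear
transform emulating inter-lead correlation. Defaults model the two study
settings the package targets: 10 s single-lead records at 500 Hz and
two-lead records at 360 Hz.

What the generator does **not** emulate: arrhythmia and disease
morphologies, respiration coupling, electrode-contact artifacts,
non-stationary heart rate. Passing tests on these cohorts demonstrates
that the pipeline's machinery is correct and self-consistent, not that its
accuracy transfers to real populations; synthetic subjects drawn from
disjoint templates are easier to separate than real people.

The end-to-end study condition used by the test suite and the acceptance
script is 20 subjects x 20 records (10/10 train/test per subject by
alternating record index), 10 s at 500 Hz, moderate noise (0.1 mV wander,
0.02 mV white noise, 0.2 spikes/s), default network parameters, median
over 5 replicate cohorts. One such run is about half a minute on one CPU,
which keeps the full suite and the acceptance script to a few minutes.

## Numerical choices

* **Edge handling of moving averages** — windows truncate at the signal
  ends (no zero padding), so constants map to themselves and baseline
  estimates carry no fabricated edge transients.
* **Beat windows** — `ceiling(w/2) - 1` samples before the peak,
  `floor(w/2)` after; an odd sample lands after the peak. Peaks whose
  window crosses the record boundary are discarded.
* **Patch vectorization** — column-major within the patch, mirrored
  exactly when reshaping eigenvectors to kernels. Any consistent pair
  works; this one is pinned and observable through the delta-kernel
  identity test.
* **Convolution** — true convolution (kernel flipped), zero-padded to
  `same` size, implemented as one matrix product of flipped kernels with
  the patch matrix and verified against an explicit double-loop oracle.
* **Eigenvector sign** — fixed so each kernel's largest-magnitude
  coefficient is positive. Binarization makes features sign-sensitive, so
  determinism across linear-algebra backends requires pinning. Exact
  eigenvalue ties keep the backend's order and are documented as unstable.
* **Heaviside at zero** — `H(0) = 0`; only strictly positive responses
  set a bit.
* **Stride rounding** — `round((1 - R) * h)` rounds half up with a floor
  of 1 (a zero stride is meaningless); block counts use
  `floor`, the only reading under which every counted block fits.
* **`pad_before_blocks`** — the block grid is conventionally counted on
  an `(m + k1 - 1) x (n + k2 - 1)` padded code image even though the
  convolution outputs are `m x n`; the default reproduces that arithmetic
  by zero-padding the code image, and the flag exposes the unpadded
  variant.
* **Degenerate inputs** — constant signals (no definable peak), all-zero
  beat vectors, constant training images, zero-variance patch scatter,
  and zero denominators in the fidelity metrics all raise explicit
  errors rather than returning infinities or NaNs.

## Open design points and how they were settled

* **One-lead records and a 784-sample target.** The averaged beat has 400
  samples per lead; the beat vector is defined as the concatenation of all
  available leads linearly resampled to the target length. This makes the
  length contract exact for any lead count and keeps 28 x 28 single-lead
  and 40 x 40 two-lead images consistent.
* **Amplitude normalization** — zero mean, unit max-abs. Normalization is
  required to compare subjects across sensors and sessions; max-abs keeps
  the R deflection at a fixed scale.
* **Multi-class SVM decomposition.** The classifier contract is
  "multi-class linear max-margin, cost configurable"; the installed
  implementation (libsvm via e1071) uses one-vs-one voting. Identification
  accuracy is also checked against its one-vs-rest confusion aggregation,
  which reduces to plain multi-class accuracy.
* **Features are raw counts.** Histograms are not normalized (the
  definition is a count histogram); an optional L2 row normalization is
  exposed on the classifier for experimentation.
* **ELM width 1000.** The hidden width of the extreme-learning-machine
  baseline is not dictated by anything structural; 1000 comfortably
  exceeds the training-set sizes used here, giving the baseline its best
  (interpolating) regime. The ensemble takes one member per seed and
  activation (sigmoid, relu, sin) with majority vote, ties to the lowest
  class id.
* **Even patch sizes are rejected.** Zero padding by `(k - 1)/2` and a
  centered patch per pixel require odd `k`; the sweep harness records
  even-`k` grid points as infeasible rather than silently shifting the
  grid.

## Limitations

* Synthetic cohorts are optimistic: templates are drawn independently, so
  between-subject variation is large by construction. Real-data accuracy
  must be established on real recordings (WFDB input is supported).
* The WFDB reader covers single-file records in formats 212 and 16 —
  enough for Holter-style archives — not the full format zoo, multi-file
  records, or annotation files.
* Feature vectors are long (`2^L2 * L1 * B`); with large `L2` a sparse
  container would be preferable to the dense matrix used here.
* The filter banks assume homogeneous image dimensions; records whose
  beat vectors fail preprocessing (no detectable peak) abort rather than
  being imputed.
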