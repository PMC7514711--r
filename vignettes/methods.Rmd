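---
title: "Methods: control-state detection from multiscale sample entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: control-state detection from multiscale sample entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asyncbci)
```

## Problem

A P300 row-column speller flashes the rows and columns of a 6x6 symbol
matrix while the user attends one cell. An *asynchronous* speller must
additionally decide whether the user is currently spelling at all: the
**control** state (attending the oddball stimuli) versus the
**non-control** state (ignoring them, e.g. reading). This package
implements a detector for that state built on a single idea: attending
rare targets makes the ongoing EEG *more irregular* than idling, and the
irregularity can be quantified per channel by sample entropy at an
appropriate time scale.

The pipeline is:

1. band-pass + common-average-reference preprocessing of the continuous
   session (`preprocess_recording()`);
2. cumulative trial extraction per spelled character
   (`extract_trials()`): trial `i` covers the samples from the character
   start up to (excluding) the onset of the last flash of sequence `i`;
3. per-channel features: the signal is decimated to scale `tau` and
   summarized by its sample entropy at embedding dimension `m` and
   tolerance factor `r` (`trial_features()`);
4. two-class LDA with leave-one-out accuracy (`loo_accuracy()`);
5. hyperparameter selection over the `(m, r, tau)` grid on a held-out
   optimization split (`grid_optimize()`), then validation curves of
   accuracy versus the number of sequences (`validate_subject()`);
6. channel-wise Wilcoxon tests with Benjamini-Hochberg correction to map
   where the regularity difference concentrates (`topo_stats()`).

## Sample entropy

For a series `x[1..N]`, embedding dimension `m` and tolerance `R`, let
`B` be the number of unordered pairs of length-`m` templates whose
Chebyshev distance is below `R`, and `A` the same count for length
`m + 1`. `sample_entropy()` offers two estimators:

* `"canonical"`: `-ln(A / B)` (Richman & Moorman);
* `"corrected"` (default): `-ln((N - m + 1) / (N - m - 1) * A / B)`, which
  multiplies the ratio by the template-count ratio. The two differ by
  exactly `ln((N - m + 1) / (N - m - 1))`, which vanishes as `N` grows;
  the test suite pins this identity to machine precision.

Choices worth making explicit:

* **Tolerance.** `R = r * sd(x)`, making the statistic invariant under
  affine transformations of the signal. By default the standard
  deviation is taken from the *decimated* series (`sigma = "per-scale"`);
  `sigma = "original"` uses the undecimated series instead. Per-scale
  normalization is the default because it keeps `r` interpretable at
  every scale even though decimation removes power.
* **Strict inequality.** Matches require distance `< R` by default
  (`strict = FALSE` gives `<=`). For continuous data the difference is a
  null set; it matters only for synthetic ties and is exposed for
  reproducibility.
* **Degenerate inputs error, never return a number.** A constant signal
  (`sd = 0`), a signal shorter than `m + 2`, or `A == 0 || B == 0` (no
  matches) raise errors; the pipeline converts them into flagged
  (`NA`) feature rows rather than fabricating values.
* The counting core is a single `O(N^2)` C++ pass that accumulates all
  template lengths `1..m+1` (and, in the grid search, all tolerances)
  simultaneously; the test suite verifies it against an independent
  dense-matrix oracle on 100 random signals.

## Multiscale entropy and the reliability criterion

`mse_profile()` evaluates sample entropy at scales `tau = 1..25`. Scale
`tau` is produced by **anti-aliased decimation** rather than
block-averaging: a least-squares linear-phase FIR low-pass of order 30
with cutoff `(1/tau) x Nyquist` (designed by an internal closed-form
least-squares routine, taps normalized to exact unit DC gain) is applied
with reflection padding and delay compensation, and every `tau`-th
sample is kept. The decimated length is `ceiling(N / tau)`.

Entropy estimates are only trusted where the Richman-Moorman guideline
`N >= 10^m` holds (`is_reliable()`). With the speller timing used here -
75 ms flashes, 100 ms inter-stimulus interval (175 ms onset asynchrony),
12 flashes per sequence, 256 Hz - the first cumulative trial has
`floor(11 * 0.175 * 256) = 492` samples, so at `m = 2` exactly 4 of the
25 scales are reliable for a single sequence, and the full 25-scale
profile becomes computable only from 5 sequences onward. The
`scripts/acceptance.R` script recomputes that threshold (the largest
sequence count at which some scale still fails, namely 4) from a
generated session.

## Classifier and grid search

The discriminant is a hand-written two-class LDA with pooled covariance
and equal priors; if the pooled covariance is singular a small ridge
(`1e-6` times the mean diagonal) is added, and a zero covariance
degenerates to nearest-mean. It is cross-checked in the test suite
against `MASS::lda` with explicit equal priors. Accuracy is always
leave-one-out, which is deterministic.

`grid_optimize()` scores each `(m, r, tau)` with `m` in `{1, 2}`,
`r` in `{0.10, ..., 0.30}` and `tau` in `1..25` (250 combinations) by averaging
the LOO accuracy over all sequence counts whose decimated length is
reliable; unreliable `(sequence, tau)` pairs are excluded from the
average, not zero-filled. Ties are broken toward the smallest `tau`,
then the smallest `m`, then the largest `r` - the cheapest computation
and loosest tolerance. The split between optimization and validation
characters (`split_dataset()`) is balanced per subject and state (30%
of 120 characters gives 36/84) and runs in an isolated RNG stream so it
never perturbs the caller's seed.

## Synthetic session generator

No public dataset accompanies the protocol, so `generate_session()`
produces sessions with a *known, tunable* control/non-control contrast.
Design goals: realistic timing and event structure, a regularity gap
concentrated at scale 2 so the grid search has a well-defined optimum,
and a single `regularity_gap` knob with `0` meaning "states identical in
distribution".

Components (all per channel; fs = 256 Hz, Nyquist 128 Hz):

* **Shared background**: an AR(2) process (coefficients 1.6, -0.64)
  giving a 1/f-like spectrum, standard deviation `noise_sd = 5`, plus
  **mask noise** in `(0.52, 0.92) x Nyquist` (amplitude 8) present in
  *both* states. The mask dominates the scale-1 statistics and is
  removed by the scale-2 anti-aliasing filter (cutoff `0.5 x Nyquist`).
* **Control**: band-limited noise in `(0.35, 0.48) x Nyquist`
  (amplitude 14) - kept at scale 2 (below the 0.5 cutoff) but removed
  from scale 3 onward (cutoff 1/3) - plus a P300-like raised-cosine
  deflection (`erp_template()`, peak 300 ms, support 200-500 ms,
  amplitude 5) after each target flash.
* **Non-control**: an amplitude-modulated 10 Hz rhythm (amplitude 6)
  whose regularity *lowers* sample entropy.

All state-dependent amplitudes are multiplied by `regularity_gap`. The
band placement makes `tau = 2` the uniquely informative scale: at
`tau = 1` the shared mask hides the contrast, at `tau >= 3` the control
noise is filtered away. Crucially, the state components are
**channel-specific** (independent noise realizations, per-channel
oscillation phase and ERP amplitude jitter): a perfectly common-mode
component would be annihilated by the common average reference. Spatial
structure comes from `gap_channel_weights` (for the standard 16-channel
montage: weight 1 on frontal/occipital channels, 0.3 elsewhere).

Two empirical properties of this design, pinned by tests:

* The entropy contrast at scale 2 rises steeply with the gap up to
  about 0.3 and then *saturates and declines* (a very strong narrow-band
  component is itself quasi-regular) while remaining clearly positive;
  classification accuracy stays monotone in the gap.
* Because the injected bands lie far above the 0.1-30 Hz band used for
  real recordings, the synthetic end-to-end experiments run with the
  common average reference only (`preprocess_recording(low = NULL,
  high = NULL)`); applying the 30 Hz low-pass would remove the synthetic
  contrast itself. The band-pass defaults remain the documented choice
  for real data.

## Problem sizes used in the test suite

The published experiment (10 subjects x 120 characters x 15 sequences x
16 channels) is too large for a test suite, so the stochastic end-to-end
tests scale it down; the sizes below are this package's choice:

* scale recovery: 20 seeded runs of 12 characters x 3 sequences x 4
  channels, uniform weights, gap 0.5, full 250-point grid -
  `grid_optimize()` must pick `tau = 2` in at least 80% of runs;
* validation: 12 characters x 15 sequences x 4 channels, gap 0.5 -
  accuracy above 0.9 at 15 sequences; gap 0 stays within generous
  chance bounds; gap 0.04 (a deliberately hard regime) shows the rising
  accuracy-versus-sequences trend;
* null statistics: 50 seeds x 4 channels at gap 0 - channel-wise
  signed-rank flags at `alpha = 0.05` within `0.05 + 2 SE`.

## Session container

Sessions are stored as a plain-text directory (`write_session()` /
`read_session()`): `meta.json` (format version, sampling rate, labels,
provenance including the full generator configuration), `characters.csv`,
`events.csv`, and `signal.csv` with samples as rows and channels as
columns, printed with 17 significant digits so the double-precision
round trip is bit-exact. A text container was chosen over a binary
scientific format to keep artifacts diffable and dependency-free; the
format is versioned so a binary backend could be added behind the same
interface.

## Limitations

* The generator is a *construct-validity* instrument, not a simulator of
  real EEG: its contrast mechanism is placed at a known scale by
  spectral design, so recovering `tau = 2` validates the pipeline's
  machinery, not the neurophysiological claim.
* Sample entropy is `O(N^2)`; profiles over 25 scales on full 15-sequence
  sessions are batch, not real-time, computations.
* The signed-rank topography pairs control and non-control characters by
  within-state order, which is arbitrary (the protocol defines no
  natural pairing); the rank-sum mode avoids the pairing at some cost in
  power.
* LDA assumes shared covariance across states; with 16 channels and few
  characters per split the covariance estimate is noisy, mitigated but
  not removed by the ridge fallback.
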