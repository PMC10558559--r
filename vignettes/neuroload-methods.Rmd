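---
title: "Methods: dynamic network and spectral evaluation of EEG workload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic network and spectral evaluation of EEG workload}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroload)
```

This vignette is the package's own account of its models and the choices
behind them: what each stage assumes, which parameters matter, what the
synthetic data do and do not emulate, and where the design was genuinely
open.

## The measurement model

A trial is a multichannel EEG recording (microvolts, channels × samples,
uniform rate; the emulated regime is a 116-channel montage at 500 Hz)
plus two per-trial outcomes: a simulator performance score on a 0–100
scale and a workload score formed by summing six questionnaire domains
each rated 1–20, so totals span 6–120. Trials nest within subjects, and
subjects differ systematically in both outcomes — every model downstream
therefore carries a per-subject random intercept, and every
cross-validation split is blocked by subject so that no participant's
trials inform both sides of a fold.

Channels are grouped anatomically: each label maps to one of 21 Brodmann
areas (the shipped `brodmann_map.yaml`, 116 channels), and each area to
one of four cortices. Two pieces of that configuration are **stand-ins**
because no measured counterpart was available to ship: the BA→cortex
grouping follows standard lobe anatomy, and the reduced 32-channel
montage is the 10–20 subset of the study montage padded with common
10–10 positions. Both are plain-text configs (`inst/extdata/`) precisely
so that a user with the true assignments can drop them in.

## Decontamination chain

Five steps, fixed order, each a pure transform:

1. **Common average reference** — subtract the across-channel mean at
   every sample. Assumes the montage samples the scalp densely enough
   that the average approximates a neutral reference.
2. **Notch** — second-order IIR notch at 60 Hz, quality factor 30
   (centre/−3 dB-width), run forward–backward. The narrow stopband
   removes line noise (measured attenuation ≈ 26 dB on a pure tone)
   while a 10 Hz tone passes within 1 dB.
3. **Band-pass** — Butterworth high-pass/low-pass cascade at 0.2–250 Hz,
   order 4 per edge (24 dB/octave), forward–backward. Zero-phase
   filtering matters here: phase distortion would corrupt the
   coherence estimates that everything downstream consumes. A 250 Hz
   edge equals Nyquist at 500 Hz, where IIR design is undefined, so the
   edge is clipped to 0.99 × Nyquist with a logged message.
4. **Artifact screen** — 1-s segments are rejected when any channel
   exceeds ±100 µV peak or when a channel's within-segment variance
   exceeds 5× that channel's median segment variance. This transparent
   amplitude/variance screen replaces proprietary blind-source-separation
   cleanup: it is deterministic, auditable, and preserves the contract
   that only clean segments reach the windowed analyses. Thresholds are
   arguments; the defaults are conventional clinical screening values.
5. **Surface Laplacian** — spherical-spline current-source-density
   estimate (spline order m = 4, Tikhonov regularization λ = 1e−5,
   50 Legendre terms). It acts as a spatial high-pass that suppresses
   the volume-conducted, spatially smooth part of the field: a uniform
   field maps to numerically zero, a point source peaks at its own
   electrode. Electrode positions default to an **idealized spherical
   template** parsed from extended 10-5 labels (row prefix →
   anterior–posterior arc fraction; digit pair → lateral fraction; `h`
   → half-step). Digitized positions can be supplied instead; the
   template is adequate because the Laplacian needs plausible geometry,
   not millimetre accuracy.

## Coherence networks

Within any segment, magnitude-squared coherence is estimated from
Welch-averaged cross-spectra over Hann-tapered sub-segments of half the
sampling rate (250 samples at 500 Hz) with 50% overlap, then averaged
over the frequency bins inside each band (theta 4–8, alpha 8–12, beta
13–35, gamma 35–65 Hz; the printed band edges leave 12–13 Hz
unassigned, and so does the package). Estimator degeneracy drives this
design: coherence computed from one unsegmented window is identically 1,
so at the 1-s analysis window three overlapping sub-segments is the
minimal defensible scheme, and the implementation refuses anything
shorter. The estimator bias for independent signals is roughly the
reciprocal of the sub-segment count; tests assert independent noise
stays below 0.3 while a shared band-limited source drives in-band
coherence toward 1. Matrices are kept weighted — no thresholding or
binarization — with the diagonal fixed at 1 and excluded from strength
and search-information computations, because self-coherence carries no
information.

## Dynamic community structure

Each retained 1-s window's coherence matrix is clustered by weighted
Louvain modularity maximization (resolution γ = 1, seeded through R's
RNG). A single Louvain run is a local optimum, so each window uses a
consensus: 100 seeded repetitions, a node co-assignment matrix, zeroing
of entries at or below the mean co-assignment expected under a
label-permutation null (a Newman–Girvan-style randomization that
preserves community sizes), re-clustering of the thresholded matrix, and
iteration until the co-assignment matrix is block-binary (cap 50
iterations, with a warning on non-convergence). On disconnected cliques
the consensus is provably seed-invariant, which the tests assert.

Louvain labels are arbitrary integers per window. Left unaligned they
would make Eq.-style flexibility meaningless — almost every transition
would "change" labels. Consecutive windows are therefore aligned by
maximum-overlap matching on the label contingency table, solved as a
maximum-weight bipartite matching; labels with no overlap get fresh
integers. This alignment is the package's most consequential numerical
choice and is deliberately prominent here.

From the aligned partition matrix:

- **flexibility** is the fraction of consecutive-window label changes
  per channel (0 = stable, 1 = changes every transition);
- the **module allegiance matrix** P gives the fraction of windows in
  which two channels co-habit a community;
- **recruitment** of a system is the mean allegiance over all ordered
  within-system pairs *including* self-pairs (the literal formula;
  P_ii = 1 slightly inflates recruitment for small systems, so
  `include_self = FALSE` is available for sensitivity analysis);
- **integration** is the mean between-system interaction, divided by
  the grand mean of off-diagonal allegiance. "Normalized interaction"
  admits several readings; dividing by the global mean is the common
  convention, and `normalize = FALSE` exposes the raw value.

## Search information and strength

Search information treats the weighted network as a random-walk medium:
a memoryless walker at node u steps to v with probability Γ_uv divided
by u's total strength. S(i→j) is −log₂ of the probability of walking
the shortest path (edge lengths −log Γ_uv); equal-length shortest paths
are averaged over, so degenerate geometries stay deterministic.
Disconnected pairs are infinite and are excluded (with a logged count)
from the per-channel averages. Per-channel search information is the
mean over reachable targets; strength is the mean off-diagonal weight
over **all** incident edges — the within-region-only variant is a
plausible alternative reading, and the region averaging happens after
either choice.

## Spectral features

PSD uses Welch averaging of 1-s Kaiser-tapered windows at 50% overlap
(1 Hz resolution at 500 Hz). The Kaiser shape parameter is β = 14, a
high-sidelobe-suppression choice; any fixed β satisfies the procedure,
so the value is an exposed argument rather than a hidden constant. Band
power is the mean PSD across in-band bins in linear (not dB) units,
absolute rather than relative — no normalization is applied because none
is part of the emulated procedure. A Parseval check (integrated PSD vs
signal variance within 15%, the window/taper bias allowance) guards the
scaling.

Feature vectors are deterministic in name and order
(`metric|region|band`, region-major then band-minor): 84 per metric
family at BA level (21 × 4), 96 in total at cortex level (6 × 4 × 4).

## Statistical layer

**Random-intercept models** are fit by REML via `lme4`, reporting Wald
normal p-values for fixed effects (matching the estimate/SE/p-value
reporting layout of the emulated analyses), a likelihood-ratio test of
the subject variance component with the ½χ² boundary correction (the
standard fix for testing a variance at the edge of its parameter
space), Efron's pseudo-R², MAE and RMSE on conditional fitted values.
Singular fits are flagged, not hidden.

**Approach A** runs forward selection inside each of 7 subject-blocked
folds: at each step add the candidate minimizing the fold's ML-fit BIC,
stop when BIC stops decreasing; keep variables selected in ≥ 2 folds;
refit on all data with Šidák-adjusted p-values (1 − (1−p)^m, m = kept
predictors). The inclusion criterion had to be chosen (the emulated
procedure does not state one); BIC is deterministic and standard. One
behavioural consequence is documented honestly: because 7 folds share
6/7 of their rows, a noise feature that happens to fit is often
re-selected across folds, so under a null outcome the kept set is small
(empty or singleton in roughly half of runs, mean kept fraction ≈ 7% of
candidates in our simulations) but not reliably empty.

**Approaches B/C** use an L1-penalized mixed model: for each λ on a
glmnet-derived grid, alternate a lasso fit of the fixed effects on the
outcome minus current subject effects with re-estimation of the variance
components from the residuals, to convergence; choose λ by BIC of the
support-refit mixed model (subject-blocked CV deviance is available by
flag); refit the selected support unpenalized for reported estimates and
p-values. An all-empty path returns an empty model rather than an error.
Before fitting, a local-outlier-factor screen (k = 20 neighbours,
classic reachability-density LOF; `"auto"` removes scores above 1.5)
drops anomalous trials. Approach C additionally restricts to the
reduced 32-channel montage; both B and C force cortex-level features,
and `run_pipeline()` validates those constraints before any computation.

## What the synthetic data emulate — and what they do not

`simulate_recording()` builds channels as independent Gaussian noise
plus **band-passed white-noise sources** shared within groups at a
stated coupling. Band-passed noise (rather than sinusoids) makes
coherence broadband within the target band and keeps PSD tests free of
line-spectrum artifacts. Groups active in different window ranges
induce genuine time-varying community structure.
`simulate_outcomes()` adds per-subject intercepts, Gaussian noise,
clipping to the 0–100 performance scale, six discretized 1–20 workload
domains summed to 6–120, and missing outcomes at a stated rate —
mirroring the unequal per-model sample sizes real trials produce. The
optional composite-performance emulation mirrors the simulator's
weighted-metric structure (weights 17.54 for five metrics, 8.77 and
3.51 for the other two, rescaled to 0–100), but the simple linear form
is the default.

What the generator does **not** emulate: 1/f background spectra,
non-stationary artifacts with realistic topographies, volume-conducted
mixing through a head model, ocular/muscle sources, or
questionnaire-domain correlation structure. Passing tests therefore
demonstrate that the pipeline's machinery is correct and recovers
planted structure under its own assumptions — not that the features are
sensitive or specific on real scalp data.

## Problem sizes and numerical conventions

The test and acceptance runs use sizes chosen to exercise every code
path at desk scale: toy graphs of 3–24 nodes; exhaustive flexibility
checks over all label sequences with T ≤ 5 and ≤ 3 labels; 200 random
connected graphs (N ≤ 8) against a path-enumeration oracle; planted
3-block networks of 18 nodes; cohorts of 8–26 subjects with 2–10 trials;
50-feature support-recovery designs at n = 200; and an end-to-end study
of 8 subjects × 4 trials × 12 s × 16 channels with 100-repetition
consensus clustering. Tolerances follow the estimator, not the test:
1e−9 bits for search information (pure arithmetic), 15% for Parseval
(taper bias), 2 SE for parameter recovery, ≥ 0.95 label agreement for
planted communities.

Degenerate inputs have defined behaviour throughout: single-channel
re-referencing, sub-Nyquist violations, too-short segments, all-rejected
artifact masks, single-region integration, disconnected node pairs,
zero-variance outcomes, and k exceeding the subject count all raise
descriptive errors; duplicate rows in the LOF screen score 1 by
convention and are never removed.

## Known limitations

- The BA→cortex grouping and 32-channel subset are documented stand-ins,
  not reconstructions of any particular lab's configuration.
- The artifact screen is deliberately simpler than blind-source
  separation; heavy ocular contamination will either survive (below
  threshold) or cost whole segments.
- Coherence is susceptible to residual volume conduction even after the
  Laplacian; imaginary-coherence-family estimators are out of scope by
  design.
- The consensus-null thresholding realizes "statistical testing against
  a degree-preserving null" as a mean-level cutoff; no α level is
  attached because none is defined for it.
- With heavily correlated features (region averages of overlapping
  channel sets), forward selection and the lasso identify *a*
  parsimonious predictive set, not a unique causal one.
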