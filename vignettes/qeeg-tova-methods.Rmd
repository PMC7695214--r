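---
title: "Methods: quantitative EEG biomarkers during the Test of Variables of Attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative EEG biomarkers during the Test of Variables of Attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qeegtova)
```

## Overview

`qeegtova` implements a quantitative EEG (qEEG) biomarker pipeline for
19-channel recordings acquired at rest and during the Test of Variables of
Attention (TOVA), a 21.6-minute continuous performance test of 648
two-second trials (324 targets, 324 nontargets, four quarters with
infrequent-target and frequent-target halves). The pipeline produces three
families of output per subject and condition (resting, correct-target,
correct-nontarget):

1. **Band power and cordance** — absolute and relative power in delta
   (1–4 Hz), theta (4–8), alpha (8–12) and beta (12–16), neighbor-averaged
   over adjacent 10-20 electrodes, z-scored across the 19 channels, and
   summed into cordance (`z_abs + z_rel`), a proxy associated with cortical
   perfusion.
2. **Covariance-matrix images** — per-trial trace-normalized scatter
   matrices `X Xᵀ / trace(X Xᵀ)` averaged over a response class, mapped to
   8-bit and histogram-equalized, giving a 19×19 image of between-channel
   interaction.
3. **A two-scale approximate-entropy score** of that image: the row-major
   361-element sequence is scanned with pattern lengths m₁ = 20 (the
   spacing of consecutive diagonal elements) and m₂ = 50 (guaranteeing
   adjacent-channel context), and the score is
   `(1/n) · ApEn(S, m₁, r) / ApEn(S, m₂, r)` where each component is the
   mean fraction of window pairs within a similarity threshold `r`.

A statistical layer (Mann–Whitney, two-way ANOVA with Bonferroni post hoc,
channelwise t-tests, Spearman correlation, ROC analysis with weighted score
combination, and bootstrap resampling of group means) evaluates the scores
as group biomarkers. Because no clinical recordings are distributed, a
seeded synthetic cohort generator is a first-class module: every stage is
tested against data whose ground truth is known by construction.

## Preprocessing

The cleaning chain follows the standard three-stage design for this kind
of recording:

* **Baseline wander**: the baseline estimate is a cascade of two running
  median filters, a small 0.04 s window followed by a large 0.2 s window
  (reflect padding), subtracted from each channel. Median filters are
  deliberately nonlinear; the subtraction removes drift below ~0.5 Hz by
  more than 20 dB while preserving a 10 Hz tone within 5%. The cost of the
  0.2 s window is that the delta band itself is strongly attenuated (to
  roughly 20% of its power) and theta/alpha gain up to ~15–25% through the
  `|1 − H|` side lobes of the subtraction; summed 4–16 Hz power stays
  within ~10–15%. Reapplying the chain moves 4–16 Hz power by up to ~20%
  more — the cascade is not idempotent — so the chain is applied exactly
  once. These are measured properties of these filter windows, not
  tunables, and the test suite asserts them at the measured bounds.
* **Line interference**: a linear-phase Hamming-window FIR band-reject
  (order 500, 60 ± 2 Hz) applied as a zero-phase frequency-domain
  multiplication. At the default order the response is ≥ 40 dB down at
  60 Hz with < 1 dB passband ripple outside ± 6 Hz.
* **EOG**: the four EOG-related channels (Fp1, Fp2, F7, F8) are decomposed
  by deflation FastICA (tanh contrast, deterministic seeded
  initialization; whitening is restricted to the numerically independent
  directions because frontal channels can be near-collinear). A component
  qualifies as ocular when more than half its power lies below 4 Hz and it
  correlates at least 0.6 with the low-pass (< 4 Hz) frontal mean; the
  best-correlated qualifying component is regressed out of every channel
  by a recursive-least-squares adaptive filter (forgetting 0.999, 3 taps).
  If no component qualifies — e.g. a blink-free recording — the input
  passes through unchanged, which keeps the operator safe on clean data.
  Trailing near-Gaussian ICA components may hit the iteration cap without
  settling; they are returned flagged, since the blink component is
  strongly non-Gaussian and converges first.

## Epoching and behavioral scores

Epochs are half-open windows `[onset, onset + 2 s)` — the full
inter-stimulus period, 19 × 512 samples at 256 Hz — with no pre-stimulus
offset, and resting recordings are cut into consecutive non-overlapping
windows of the same shape so both states feed identical covariance
machinery. The five TOVA metrics are omission rate, commission rate, mean
response time, response-time variability (SD over correct-target
latencies), and d-prime computed as `z(hit) − z(false alarm)` with both
rates clipped to `[1/(2N), 1 − 1/(2N)]` before the quantile — the standard
correction, configurable in principle but fixed here for comparability.

## Spectral estimation choices

Band power is a per-epoch periodogram with a power-normalized Hann taper,
summed over half-open bands, Parseval-normalized so a sinusoid of
amplitude A contributes A²/2. Any Parseval-consistent estimator satisfies
the same contracts. Neighbor averaging uses a shipped symmetric 10-20
adjacency table (the F3 row is exactly `{Fp1, F7, Fz, C3}`, reproducing
the reorganization rule `(F3+Fp1+F7+Fz+C3)/5`); the rest of the
table is the package's convention and can be overridden with any symmetric
map. Z-scores are taken after neighbor averaging, per band, separately for
absolute and relative power, with the population (n) SD — the n vs n−1
choice cancels in all group comparisons. Cordance is consequently
invariant to global gain changes of the raw signal.

## The entropy score and its similarity threshold

The two-scale score uses Chebyshev window distance and counts self-matches
(the classical convention, keeping both components strictly positive), and
`r` defaults to 0.2 × SD of the sequence, the classical approximate-entropy
choice; an absolute `r`, Euclidean distance, exclusion of self-matches, and
disabling the 1/n prefactor are all available, and every score records the
`r` actually used plus both raw components, so any alternative reading of
the score definition can be reconstructed from the stored pieces. The
score is computed on the equalized image by default (matching the pipeline
order: normalize → 8-bit → equalize → entropy); `image8` and `raw` sources
are selectable.

Two properties are worth stating explicitly. First, with self-matches
included, a structureless (noise) image sits at the floor
`ApEn(m) = 1/(n−m+1)` for both scales, so the ratio is bounded and the
score is minimal; repetition that survives at the one-row scale but not
across several rows raises the m₁ component while the m₂ component stays
floored, which is exactly the "color gaps in adjacent channels" phenotype
the score is designed to grade. Second, because histogram equalization is
a rank transform, only rank-stable structure in the covariance pattern can
produce window matches — continuous-valued covariance estimates with no
repeated structure are driven to the floor regardless of how smooth they
look. This observation shaped the synthetic generator below.

## The synthetic cohort generator

The generator emulates what the analysis needs to see, not cortical
physiology:

* **Spatial structure.** Channels are driven by two correlated regional
  latent sources (anterior/posterior, correlation 0.5), one per frequency
  band, scaled per channel to a band-power profile. The
  `covariance_regularity` knob (per state, in `[0,1]`) controls the
  contiguity of the channel→source assignment: at 1 the assignment is the
  contiguous block pattern, giving covariance images whose pixel classes
  are exactly tied and whose row pattern repeats at both entropy scales
  (low score); lower values apply seeded cross-label transpositions (up to
  4 at regularity 0) that fragment the blocks, so repetition survives only
  at the one-row scale (high score). Every transposition exchanges two
  channels with *different* labels, so each step fragments the pattern by
  a comparable amount — this keeps the knob's response monotone with
  modest seed-to-seed variance. Exact ties are the deliberate design:
  duplicate-source channels yield exactly duplicated covariance pixels,
  making the regularity signal immune to estimation noise and to the rank
  amplification of equalization.
* **Band topography.** The default profiles carry a realistic gradient
  (occipital alpha dominance, frontally weighted theta, and a frontal
  theta elevation — strongest at F7 — in the patient arm, which the
  cordance layer detects). A spatially uniform profile
  (`uniform_band_profile()`) is used where the entropy contrast is under
  study, because per-channel spectral gradients break the exact pixel
  ties; this trade-off is documented rather than hidden.
* **Artifacts.** Frontally loaded blink transients (300 ms raised-cosine
  pulses, Poisson events, slight left/right asymmetry), sub-0.5 Hz drift,
  and a 60 Hz sinusoid, each with profile-controlled amplitude, cover
  every artifact class the preprocessing removes.
* **Behavior.** Targets are omitted i.i.d. at the profile's omission rate,
  latencies are truncated normal on the 100–1900 ms response window (the
  simplest distribution matching the target group moments), and
  nontargets are pressed at the commission rate. The arm defaults are the
  reference group values (omission 1.70 vs 7.29%, commission 2.06 vs
  3.33%, RT 363 ± 47.8 vs 450 ± 92.5 ms, BDI 6.22 ± 6.76 vs 30.8 ± 11.7).
* **Quarter ratios.** The test format fixes only the totals; the
  default quarter target fractions (0.225, 0.225, 0.775, 0.775), rescaled
  by largest remainder to exactly 324 targets, implement the standard
  infrequent-then-frequent TOVA halves and are configurable.

What the generator does *not* model: biophysical neural masses, volume
conduction geometry, medication effects, age/gender structure, or 1/f
background spectra. Passing tests demonstrate that the pipeline recovers
known structure of this generative family; they do not validate clinical
performance on real recordings. In particular, with the default
gradient-and-artifact profiles the entropy contrast is much weaker than
with the uniform preset, because artifact-removal residues and spectral
gradients perturb the exact pixel ties the score keys on.

## The crossover preset

`crossover_spec()` is the package's documented reference operating
point for entropy parameter recovery: control regularity 0.55 (rest) /
0.95 (task); patient 0.75 / 0.30; between-subject jitter SD 0.10 (both
states moved together); uniform band topography; zero artifact amplitudes.
The separations were calibrated once against the generator's measured
regularity→score response so that, at 18 + 18 subjects, (i) the task-state
group contrast is large (subject-level separation of roughly three
within-group SDs), (ii) the resting contrast is small, *reversed* (control
above patient), and usually non-significant under the Bonferroni post hoc,
and (iii) the group-mean ordering — patient > control for target and
nontarget, control > patient at rest — reproduces in ≈ 98% of seeded
cohorts with a task ROC AUC near 0.95. The acceptance checks run 100 such
cohorts at reduced problem size (64 Hz sampling, 40 trials, 60 s rest,
18 + 18 subjects — sizes chosen to keep one cohort under ~2 s without
changing the contrast mechanics, which depend on exact ties rather than
sample length).

## Statistical layer conventions

* Mann–Whitney is exact for ≤ 20 untied observations per arm, otherwise a
  tie-corrected normal approximation; two-sided throughout.
* The two-way ANOVA treats condition as a between-observation factor (as a
  plain two-way layout does); the result carries a note that the
  within-subject structure of condition is ignored. Post hoc contrasts use
  the pooled residual mean square with Bonferroni-adjusted p values and
  CIs, the Prism-style post test. Effects with numerically zero sums of
  squares report F = 0, p = 1 rather than 0/0.
* ROC: AUC is the rank (Mann–Whitney) statistic over n₊n₋; the SE is
  Hanley–McNeil; the operating cut-off maximizes Youden's J midway between
  adjacent scores (a documented substitution for the original stepwise
  discriminant selection), with exact binomial CIs on sensitivity and
  specificity at the cut-off.
* The combined score is `apen + w · omission%` on raw scales, swept over
  w ∈ {0, 0.1, …, 1}; a standardized mode removes the unit dependence.
  The sweep reports the full AUC grid and the argmax, never a fixed
  weight.
* The bootstrap draws B = 1000 resampled means per group × condition cell,
  reports percentile CIs per cell, Gaussian kernel densities (Silverman's
  rule), a one-way ANOVA across cells with all 15 Bonferroni pairwise mean
  differences and adjusted CIs, and per-condition ROC on the bootstrapped
  means. Percentile intervals on n = 18 Gaussian cells cover the true mean
  at roughly 92–95%, the expected mild undercoverage of the percentile
  method at this sample size.

## Numerical conventions and degenerate inputs

Half-open frequency bands and epoch windows; 8-bit mapping rounds half up;
equalization uses the discrete CDF over 256 levels with the lowest
occupied level as the reference (a constant image maps to all-zero and is
flagged); an all-zero epoch (zero trace) is an error; a channel with zero
total power yields NA relative power; zero cross-channel variance yields
NA z-scores; a session with no correct target reports NA response time
rather than zero; a constant sequence resolves `r = 0.2 × SD = 0` to the
smallest positive number so the constant-image score is exactly the
1/n-scaled unit ratio. All randomness flows through explicit seeds; every
seeded operation restores the caller's RNG state, so operations are pure
functions of (inputs, seed).

## Problem sizes used by the test suite

The default test run simulates at full acquisition parameters only where
the contract depends on them (geometry, preprocessing operating points at
256 Hz) and otherwise at reduced sizes: 64 Hz cohorts for parameter
recovery (100 cohorts of 18 + 18), 10,000 null simulations for type-I
calibration, 500 replicates for bootstrap coverage, and 50 random
sequences for the brute-force entropy oracle. `scripts/acceptance.R`
recomputes the same quantities from scratch at the same sizes.

## Known limitations

* The entropy contrast requires rank-stable covariance structure; on
  recordings whose covariance has no repeated structure (including the
  generator's own gradient-topography default), scores cluster near the
  structureless floor and discriminate weakly.
* The median-cascade baseline filter materially attenuates the delta band;
  delta-band cordance is computed but inherits this attenuation.
* The resting/task recordings of a subject are generated independently
  given the profile; there is no within-subject spectral identity beyond
  the regularity jitter being shared.
* EDF input is not supported; the interchange format is long CSV
  (`time_s, channel, uV`).
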