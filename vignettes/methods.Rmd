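---
title: "Methods: multimodal mapping of cognitive circuits in tumour-infiltrated cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal mapping of cognitive circuits in tumour-infiltrated cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Diffuse gliomas infiltrate cortex that may remain functionally active. This
package implements a three-level analysis of whether such tissue
participates in large-scale cognitive circuits:

1. **Local electrophysiology.** Intraoperative strip ECoG during rest,
   simple counting ("easy") and switch counting ("hard") is reduced to
   per-electrode high-gamma (70–250 Hz) power contrasts, with a
   loop-rotation permutation test for significance.
2. **Whole-brain connectivity.** Resting-state BOLD seed maps around
   tumour electrodes are Fisher-z transformed, smoothed, projected to a
   spherical surface, and compared to a functional parcellation with a
   spin permutation test.
3. **Cohort statistics.** Tumour–network connectivity (mean correlation of
   tumour voxels with a network's mean timeseries, Bonferroni-thresholded)
   is related to tumour location and longitudinal cognitive outcomes with
   linear models, and electrode-level task responses are related to
   network connectivity with a grid of linear mixed-effects models.

Patient recordings of this kind cannot be shared, so the package ships
synthetic-data generators with planted ground truth for every stage; all
tests and the acceptance script run exclusively on synthetic data.

## ECoG preprocessing

The stage order is fixed: downsample → bipolar re-reference → notch →
band-power → trial segmentation. Choices a user may care about:

* **Downsampling** (default target 2 kHz) anti-aliases with an 8th-order
  Butterworth at 80 % of the new Nyquist before decimation; the target
  rate must divide the raw rate. Markers are rescaled flooring onsets and
  ceiling offsets so no labelled sample is lost.
* **Bipolar derivation** subtracts adjacent electrodes along each strip
  (k minus k+1), so a strip of m electrodes yields m−1 channels and any
  common reference cancels exactly. For this reason the generator does not
  model the scalp-reference subtraction of the acquisition chain: it is
  algebraically invisible to everything downstream.
* **Notch filtering** places an IIR biquad (quality factor 30) at every
  integer harmonic of each base (default 50 Hz mains and a 79 Hz equipment
  line) below Nyquist, run forward–backward for zero phase. Narrow notches
  keep high-gamma content between harmonics essentially untouched (a
  120 Hz probe tone passes at >90 % RMS while 50/79/100 Hz are attenuated
  below 5 %).
* **Band power** is the squared magnitude of the analytic (Hilbert) signal
  of the zero-phase 4th-order Butterworth band-limited data. For very
  narrow normalised bands (delta or alpha at 2 kHz) the direct 8-pole
  bandpass is numerically unstable; the implementation detects non-finite
  output and transparently substitutes an equivalent cascade of 4th-order
  low- and high-pass sections. All filtering uses 1 s reflection padding;
  the segmentation trims (≥1 s) then discard any residual edge transient.
* **Trial trimming** compensates manual marker placement: rest trials lose
  2 s at each end, easy trials 1 s at each end, and hard (switch) trials
  1 s at each end plus 3 s extra at the start covering the initial easy
  phase of the switch task. The underlying description of the task-trial
  exclusion ("one second from each task trial") is ambiguous between one
  end and both; we trim both ends, mirroring the rest rule, because
  reaction-time error affects onset and offset marking alike.

## The rotation permutation test

For each electrode and contrast, all trials of the two contrast conditions
are concatenated in recorded order into a loop (last sample joined to
first). One uniform integer jitter in {1, …, L−1} is drawn per rotation
and shifts *every* trial marker around the loop, after which condition
means and the percentage signal change, PSC = (p₁/p₂ − 1)·100, are
recomputed. This preserves trial lengths and temporal autocorrelation
exactly. Design points:

* Jitter granularity is a single sample — the finest faithful choice.
  Jitter 0 (the identity) is excluded from the null; when the requested
  rotation count reaches L−1 the implementation enumerates every distinct
  shift, making the null exact (and testable against brute force).
* For the easy > rest contrast the loop includes the rest trials: both
  conditions of a contrast must contribute, otherwise the rest mean could
  not be recomputed under rotation.
* Two-tailed p = 2·min(r_low, r_high) with the finite-sample
  (count+1)/(n+1) correction, so p is never 0. A constant loop is flagged
  degenerate and returns p = 1.
* The default rotation count is 100,000; calibration tests and the
  acceptance script use 2,000 rotations and 200 electrodes, which bounds
  the Monte Carlo error on the rejection rate at ±0.032 while keeping the
  run inside a few minutes on one core.

## Seed-based connectivity and the spin test

Electrode coordinates are snapped to the nearest grey-matter/tumour voxel
(Euclidean, world mm); distance ties at voxel precision are broken by
preferring the candidate whose spacing to already-snapped neighbours is
closest to the 10 mm strip geometry. Seeds are 2.5 mm spheres intersected
with the parenchyma mask. The seed's mean timeseries is Pearson-correlated
with every parenchyma voxel; r is clipped to ±(1−10⁻⁷) before the Fisher
transform so maps stay finite, and smoothing (5 mm FWHM default) uses
masked normalised Gaussian convolution so values never bleed across the
parenchyma boundary. Zero-variance voxels get r = 0 and are counted in the
map's provenance.

Surface projection is nearest-voxel sampling onto a synthetic icosphere
with a declared world embedding, replacing subject-specific surface
registration, which is out of scope; the spin test only needs values on a
sphere. Vertices farther than 3 mm from parenchyma are masked invalid.

The spin test rotates the *map* (never the parcel labels) with uniform
random rotations (unit-quaternion draw), resamples by nearest vertex, and
compares each network's observed median against the null of surrogate
medians. Invalid vertices are excluded on both sides; a surrogate in which
a network loses all valid vertices contributes no null draw (the count is
reported). The two-tailed p uses the same tie-inclusive +1-corrected
convention as the rotation test, for internal consistency.

**A known limitation follows from that convention.** For a *binary
indicator* map of one parcel among K = 7 of similar size, the null
distribution of that parcel's median is concentrated on {0, ½, 1}, and the
probability that a random rotation maps a cap of area fraction 1/7 onto
more than half of itself is ~0.08–0.10 regardless of mesh resolution. The
tie-inclusive two-tailed p therefore cannot fall below ~0.15 in this
configuration, and the package's acceptance suite records this expectation
as failing by design. A strict-tail (percentile) convention would flag the
parcel, but it is anticonservative under ties and assigns near-zero p to a
constant map, which we consider worse. On continuous (smooth) maps — the
realistic case — ties are absent, the two conventions coincide, and the
test is calibrated: parcel-uncorrelated smooth maps reject each network at
the nominal .05 rate within binomial error.

## Tumour–network connectivity and the cohort models

Tumour voxels overlapping the network mask are excluded (their count is
kept as a covariate); remaining voxels are correlated with the network's
mean timeseries, p-values come from the exact t transform
t = r·√((n−2)/(1−r²)), and voxels survive at p < α/m (Bonferroni over the
m tested voxels). The mean r over survivors is the patient's
tumour–network connectivity; zero survivors is a legal outcome (the
statistic is absent, not an error).

The association layer fits:

* a 14-model grid (2 contrasts × 7 networks) of linear mixed-effects
  models, PSC ~ connectivity with a participant random intercept only — a
  handful of participants cannot support random slopes. Estimation
  delegates to `lme4`; the connectivity term is tested with a Type II Wald
  χ² on 1 df, computed as (estimate/SE)², which a test cross-checks
  against `car::Anova`. Singular fits are flagged, never dropped.
* a location model (connectivity ~ location + hemisphere + overlap +
  antiseizure + age + gender) and outcome models (follow-up score ~
  pre-op score + connectivity + location + hemisphere + timepoint + age +
  gender), with dummy-coded categoricals at reference levels frontal /
  left / female / no / month 12. Standardised estimates z-score the
  response and continuous predictors and leave dummies at 0/1, so dummy
  coefficients read as shifts in response-SD units. The sensitivity
  variant drops patients whose latest assessment was immediately
  post-operative.

## Synthetic data: what it emulates and what it does not

* **ECoG** (`simulate_ecog`): pink (1/f, default exponent 1) broadband
  background, sinusoidal line components at 50 and 79 Hz, and a
  band-limited 70–250 Hz carrier whose envelope power is multiplied by
  condition factors during trials. Because the effect is multiplicative on
  power, the planted PSC has the closed form (factor−1)·100, which makes
  recovery assertable analytically. The in-band share of the 1/f
  background dilutes recovered PSC slightly; recovery tests therefore use
  a low-noise setting. Defaults follow the emulated protocol: a rest
  block of minutes and 2–5 repeats of each counting task, sampled at
  2 kHz after downsampling.
* **BOLD** (`simulate_bold`): a 20×20×20 grid (2 mm voxels, 200 volumes,
  TR 1.06 s) with an ellipsoidal parenchyma, K = 7 contiguous network
  cells each loading on a unit-variance latent course, and a spherical
  tumour whose voxels couple to chosen networks; the population
  correlation of a tumour voxel with course k is
  w_k/√(Σ_j w_j² + σ²), verified by simulation. The real acquisition is
  emulated in structure, not size. No haemodynamic convolution, motion,
  or neurovascular uncoupling is modelled — passing tests show the
  statistics behave as designed, not that gliomas behave like the
  generator.
* **Surface** (`make_icosphere`, `make_parcellation`): an icosphere
  (10·4^s + 2 vertices) with a Voronoi parcellation from random seed
  vertices; `method = "farthest"` gives similar-sized parcels when a
  balanced layout is needed.
* **Cohort** (`simulate_cohort`): location-shifted connectivity,
  demographic categoricals, and a follow-up score from a linear model
  whose continuous covariates enter z-scored — so planted coefficients
  are directly comparable to the standardised estimates the fitters
  report.

Every generator is a pure function of its spec and seed.

## Numerical and interface conventions

* Voxel indices are 0-based in all file formats and affine arithmetic
  (the NIfTI convention); in-memory R arrays are 1-based and conversion
  happens only through the affine helpers.
* EDF output quantises to 16 bits between per-channel physical bounds
  (relative error < 10⁻⁴ for typical microvolt ranges); the delimited-text
  format is lossless and is the reference in round-trip tests.
* Surfaces use a CSV representation (vertex, face, label tables) rather
  than GIFTI, for which no reader is available in the package's
  dependency set.
* Every stage-output CSV begins with a comment header recording the RNG
  seed and a config digest, so stochastic stages can be replayed.
* Problem sizes in the test-suite calibrations (200 electrodes × 2,000
  rotations; 200 spin replicates × 500 spins on a 162-vertex sphere) were
  chosen to bound Monte Carlo error meaningfully while completing in
  minutes on a single core.
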