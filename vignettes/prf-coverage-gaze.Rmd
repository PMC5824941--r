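---
title: "Population receptive field coverage and gaze bias: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population receptive field coverage and gaze bias: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prfgaze)
```

prfgaze implements a complete synthetic-data pipeline for studying how the
visual field is represented by cortical regions — population receptive
field (pRF) modelling from bar-sweep fMRI mapping, visual field coverage
(VFC) statistics, and a complementary eye-tracking analysis of where
different participant groups fixate on stimuli. This vignette explains the
models, the tunable parameters and their defaults, the numerical choices,
and what the synthetic generators do and do not emulate.

## The CSS pRF model

Each voxel's receptive field is an isotropic 2D Gaussian in visual-field
coordinates (x rightward, y upward, origin at fixation, units of degrees of
visual angle, dva) with centre $(x, y)$ and width $\sigma$. For a binarized
stimulus movie $S(\cdot, t)$, the compressive spatial summation (CSS) model
produces the neural drive

$$ d(t) = \Big( \sum_{\text{pixels } p} S(p, t)\, G_{x,y,\sigma}(p) \Big)^{n}, $$

with exponent $n \in (0, 1]$ capturing subadditive spatial summation
($n = 1$ recovers the classic linear pRF). The BOLD prediction is
$g \cdot (d \ast h)$, a causal convolution with the haemodynamic response
function (HRF) scaled by a gain $g$. Because the exponent is applied before
spatial pooling is complete, a compressive voxel responds over a wider
region than $\sigma$ suggests; the *effective size* $\sigma / \sqrt{n}$ is
the width of the equivalent linear Gaussian, and it is this quantity the
package reports as `size` (plain `sigma` is stored alongside so either
convention can be analysed).

The HRF is not estimated per voxel: a canonical double-gamma kernel (peak
delay 6 s, undershoot delay 16 s, unit dispersions, undershoot ratio 1/6,
32 s support) is sampled at the TR and peak-normalized, shared across
voxels and participants.

### The bar-sweep protocol

The default stimulus reproduces an 8-sweep mapping run: a 2 dva wide bar,
long enough to span the 7 dva radius field, at orientations 0/45/90/135
degrees, each swept in the two directions orthogonal to the bar. The bar
traverses the field edge-to-edge in 12 equal steps, with centres spanning
$[-(r - w/2),\, r - w/2]$ so the full bar always lies within the stimulated
span; a pixel is "on" when its centre falls inside both the bar and the
field disc. Six blank frames follow the sweeps so one run is 102 frames at
TR 2 s (3 min 24 s). Runs contain no interleaved blank periods — the blank
count is an argument for protocols that need them.

### Fitting

`fit_prf()` is a two-stage estimator. Stage one is an exhaustive grid
search over centres (15 x 15 over the field), log-spaced widths from the
model's floor (0.21 dva) to the field radius, and exponents
{0.25, 0.5, 0.75, 1}; for each candidate the gain is solved in closed form
as the positive least-squares projection of the timecourse on the
unit-gain prediction (candidates with non-positive projection score zero).
Ties break to the first candidate in deterministic grid order, so results
are independent of evaluation order. Stage two refines the best grid point
with bounded L-BFGS-B over $(x, y, \log\sigma, n)$, with $\sigma$ bounded
below by the floor and $n \le 1$. Variance explained is the coefficient of
determination about the observed mean, clamped at zero from below (clamped
fits are flagged). The three standard exclusion rules are applied after
fitting: variance explained above 5%, centre eccentricity at most 7 dva
(a centre exactly on the field edge is retained, since the exclusion is
for centres strictly outside the field), and sigma strictly above the
0.21 dva floor.

### What recovers well, and what does not

On synthetic populations at 10% noise (four simulated runs averaged
voxel-wise, the assumed analysis practice), centres recover to ~0.01 dva
and effective size to ~3% (median). Raw $\sigma$ recovers to roughly 10%:
$\sigma$ and $n$ trade off along a ridge on which predictions are nearly
identical — the fitted optimum always explains at least as much variance
as the generating parameters, yet noise moves the optimum along the ridge.
Errors in $\sigma$ and $n$ are correlated near 0.99 while their ratio
$\sigma/\sqrt{n}$ stays pinned. This is why downstream coverage and
size–eccentricity analyses are built on the effective size.

A related calibration note: with a single 102-frame run, the maximum
variance explained over ~9000 correlated grid candidates on pure white
noise frequently exceeds the 5% threshold — the threshold is only a weak
filter at that length. The package's null-calibration checks therefore fit
against the full 4-run session protocol (408 frames), where pure noise
essentially never crosses 5%.

## Visual field coverage

A region's VFC is built from its filtered fits: each voxel contributes a
unit-peak Gaussian at its centre with width equal to its effective size.
`roi_coverage()` combines voxels with a bootstrap: each of 50 iterations
draws n voxels with replacement from the n-voxel ROI, combines member
densities pointwise, and renormalizes the combined map to peak 1; the
final map is the mean over iterations, renormalized again. Renormalization
happens per draw (the final renormalization is then almost a no-op); with
a singleton ROI the procedure is exactly deterministic.

Two combine rules are implemented because both appear in practice: `mean`
(average density across pRFs, the default) and `max` (maximum pRF
density). They produce different-looking maps — max emphasises any
coverage, mean emphasises agreement — so comparisons should state the rule
used.

Group maps average per-participant maps pointwise after mirroring
right-hemisphere maps over the vertical meridian (both hemispheres then
share the contralateral convention). The group average is deliberately not
renormalized: inputs are already peak-1, and renormalizing would hide
between-participant disagreement.

Coverage is summarised three ways:

* **Extent**: the map is binarized at 0.01 (values at or above the
  threshold count as covered, since values below it are zeroed) and the
  covered proportion of in-field grid points is scaled by the stimulated
  area $\pi r^2$ ($r = 7$), giving square dva. Extent is monotone
  nonincreasing in the threshold.
* **Centre of mass**: the density-weighted centroid over in-field points;
  its distance from the origin indexes foveal bias.
* **Jackknife SE**: group-level uncertainty uses the leave-one-out
  jackknife, $\sqrt{\frac{n-1}{n}\sum_i (\hat\theta_{(i)} -
  \bar\theta)^2}$, which reduces to the classical $sd/\sqrt{n}$ for the
  mean. The resampling description this implements ("leaving out
  participants on each fold") is ambiguous between leave-one-out and its
  complement; leave-one-out is the standard estimator and was chosen.

The default coverage grid is 128 x 128 cell centres over $[-7, 7]^2$ dva.
Halving the cell size changes extent and centre-of-mass by less than one
coarse cell's contribution.

## Group statistics

`size_ecc_fit()` regresses effective size on eccentricity, weighting each
voxel by its variance explained; per-participant slopes and intercepts
are averaged downstream. With equal weights it reduces to ordinary least
squares.

`ks2d_two_sample()` compares two bivariate samples with the
two-dimensional two-sample Kolmogorov–Smirnov statistic: the largest
absolute difference between the samples' empirical fractions over the
four open axis-aligned quadrants anchored at every data point of either
sample. The default p-value is by label permutation (the statistic is
recomputed under random relabellings, vectorised into a single matrix
product); the classic large-sample approximation with the
correlation-based effective-sample correction is available as
`p_method = "asymptotic"`. The statistic is invariant under any common
translation or axis-wise scaling of both samples.

What to feed the test is a genuine methodological choice: the source
analyses compared coverage across groups without specifying the sample
construction. `coverage_to_points()` draws density-weighted grid points
from each participant's map (500 per map by default) and pools within
group; the choice and seed are recorded in pipeline metadata.

## Gaze analysis

Raw gaze streams are cleaned by `scrub_blinks()`: every sample within a
100 ms pad on either side of a blink is dropped, using half-open windows
`[start - pad, end + pad)` with overlapping windows merged. Fixations
(pre-segmented; event detection is out of scope) are accumulated as a
duration-weighted histogram on the 768 x 1024 screen grid, smoothed with
a Gaussian filter of sigma 18.75 px, and max-normalized per participant.

The **adult fixation zone** (AFZ) is defined per stimulus as the pixels
where at least 70% of adults show presence — an adult "fixates" a pixel
when their normalized density exceeds 0.01 (this presence threshold is
not stated in the source analyses and is exposed as a parameter). The
alternative reading — thresholding the group-average density at 0.7 — is
available by thresholding `group_density()` directly; the
fraction-of-adults form was chosen as the one matching the "70% of adults
or greater fixated" description.

Child deviation is scored two ways:

* **Outside-AFZ ratio**: fixation time outside the AFZ over total
  fixation time, per child and stimulus, compared against the 30% chance
  level implied by the 70% definition. A per-fixation-count variant is
  available.
* **Bias vectors**: per stimulus, the vector from the adult centre (the
  centre of mass of the AFZ-restricted adult density — density-weighted,
  rather than the unweighted mask centroid) to the child density's centre
  of mass, converted once to visual-field convention (y up). The screen
  stores y downward; a single conversion utility owns the flip, and all
  vector and quadrant logic runs in field convention.

`null_quadrant_test()` measures each vector's angular distance from the
null quadrant (lower-left for faces, lower-right for words): zero inside
the quadrant, otherwise the wrapped distance to the nearest quadrant
boundary — a vector 15 degrees into the upper-right quadrant is 105
degrees from the lower-left quadrant. Distance to the quadrant bisector
was rejected as inconsistent with "distance from the quadrant". Uniformly
random angles occupy any quadrant 25% of the time, the chance level the
test reports alongside a one-sample t-test of the distances.

## Synthetic generators: what they emulate

`sample_ground_truth_prfs()` draws voxel populations whose effective size
increases linearly with eccentricity (default slope 0.2, intercept 0.5
dva, Gaussian scatter 0.1 dva) with eccentricities uniform over
0.5–6.5 dva and polar angles uniform over the hemifield contralateral to
the hemisphere label. The CSS exponent is held at 0.5 — a mid-range value
for ventral visual areas — and $\sigma$ derived as
$\text{size}\cdot\sqrt{n}$. Gains are uniform on 0.5–1.5.
`simulate_bold()` adds independent Gaussian noise per timepoint; temporal
autocorrelation is deliberately omitted, so tests passing here do not
certify behaviour under realistic fMRI noise spectra, only the
correctness of the estimator and its statistics.

`simulate_gaze()` scatters fixations isotropically (default sd 25 px,
about 0.9 dva at a typical viewing geometry) around each stimulus centre
plus a group-level offset, with durations uniform on 150–600 ms and 40
fixations per stimulus per participant — a realistic free-viewing budget
for a several-second exposure. It does not model saccade dynamics,
centre-of-gravity landing biases, or stimulus-dependent salience; it
exists to give the density/AFZ/bias machinery a ground truth. Where a
test needs to resolve a small systematic tolerance (for example the 2 px
bias-vector round-trip), the harness raises the fixation count so the
centre-of-mass estimator's own Monte-Carlo error
($\approx \text{spread}/\sqrt{N}$) is well below the tolerance; this is a
sample-size choice, not a change to the emulated conditions.

## Problem sizes and determinism

The test-suite and acceptance harness sizes are chosen to exercise each
property at meaningful scale: 200 voxels for parameter recovery, 100
noise voxels for null calibration, 200 simulations x 199 permutations for
p-value uniformity, 2000 bootstrap iterations against exact composition
enumeration on 3-voxel ROIs, and 100,000 uniform angles for quadrant
occupancy. Every stochastic stage takes an explicit seed; the pipeline
derives a named seed per stage from one master seed, so a fixed
configuration reproduces every artifact bit for bit, as recorded in the
run manifest (config hash, stage seeds, version).

## Known limitations

* No surround suppression (difference-of-Gaussians), spatial/temporal
  frequency, or attention terms in the pRF model.
* The raw $\sigma$/$n$ split is weakly identified at realistic noise;
  analyses should use effective size (the package's `size`).
* Independent Gaussian BOLD noise; no physiological confounds, motion,
  or slow drift.
* Gaze events arrive pre-segmented; no I-VT/I-DT parsing from velocity.
* No neuroimaging file-format ingestion: inputs are plain tables and
  array containers by design.
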