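---
title: "Measuring hemispheric laterality: mirror, threshold-bootstrap and Doppler interaction methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring hemispheric laterality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latmirror)
```

## The problem

A laterality index (LI) is a signed scalar summarising which cerebral
hemisphere dominates a cognitive function, conventionally with positive
values meaning left dominance. `latmirror` computes LIs from two kinds of
data:

* volumetric t-statistic maps from task fMRI, registered to a
  left-right-symmetric grid, via two estimators — the threshold-bootstrap
  ("toolbox") LI and the threshold-free flip-and-subtract ("mirror") LI;
* bilateral cerebral blood-flow-velocity (CBFV) recordings from functional
  transcranial Doppler ultrasound (fTCD), via the side-by-period-of-interest
  interaction of an additive regression model.

Each estimator returns an estimate with a 95% confidence interval, and an
individual is categorised **left**-lateralised if the lower bound exceeds
zero, **right** if the upper bound is below zero, and **bilateral**
otherwise. The category is a property of the interval, not the point
estimate: a method with wide intervals will call more people bilateral at
identical point estimates, which is the central between-method contrast the
package quantifies.

## Conventions that everything else depends on

**Left is world x < 0.** Anatomical side is resolved through the
voxel-to-world affine (the NIfTI RAS+ convention), never from array storage
order, because on-disk orientation varies while the flip and midline logic
is anatomical. The affine must map exactly one, non-oblique storage axis to
world x.

**Grid symmetry.** Mirror operations pair each voxel with the voxel at the
negated world x. They refuse to run unless every voxel centre pairs across
x = 0 within 0.1 voxel widths, because on an asymmetric grid the pairing
silently associates non-homologous tissue.

**Midline exclusion.** A band of ±5 mm around the midsagittal plane is
excluded from all region-of-interest (ROI) masks before any LI is computed;
voxels there mix signal from the two medial surfaces. The interval is
closed: a centre at exactly |x| = 5 mm is excluded. The literature does not
fix the boundary case; the closed choice is this package's convention and
is applied identically everywhere.

## The toolbox (threshold-bootstrap) LI

The conventional LI is $(L - R)/(L + R)$, where $L$ and $R$ are summed
suprathreshold statistic values per side. Because the result depends
strongly on the threshold, the bootstrap procedure integrates over a grid
of thresholds:

1. 20 equally spaced thresholds from 0 to the in-mask maximum t
   (inclusive endpoints, spacing $\max/19$);
2. at each threshold, values strictly above it are collected per side;
   thresholds leaving fewer than 10 voxels on either side are discarded
   (a state, not an error);
3. per retained threshold, 100 resamples with replacement per side, each of
   `max(1, round(0.25 n))` values; an LI is computed for every left × right
   resample pair (100 × 100 = 10,000 LIs) from the summed values;
4. per-threshold 25% trimmed means (count-based: drop `floor(0.25 n)` from
   each end) are combined across thresholds — by default the
   threshold-weighted mean $\sum_i t_i \bar{LI}_i / \sum_i t_i$.

The 95% CI pools the trim-retained (middle 50%) bootstrap LIs of every
retained level, weighting each value by its level's threshold, and takes
the 2.5th/97.5th percentiles of the pooled weighted distribution (inverse
of the right-continuous weighted ECDF, weights normalised to one). Because
every level contributes the same number of values, the weighted mean of the
pooled distribution equals the threshold-weighted combine exactly; the test
suite asserts this to 1e-10 on every run.

Consequences worth knowing:

* threshold 0 necessarily carries zero weight in the weighted mean and
  histogram;
* voxels with negative t can never exceed a non-negative threshold — the
  method is structurally blind to deactivation, and altering negative
  voxels leaves every output bit-identical;
* multiplying the map by k > 0 rescales the threshold grid by k, leaving
  all memberships and LIs unchanged;
* whether the source implementation sums or averages resampled values is
  not documented; summation is the default here (resample sizes already
  encode each side's voxel share) and `toolbox_config(statistic = "mean")`
  provides the alternative;
* whether the pooled histogram uses trimmed or untrimmed per-level LI sets
  is also open; the trimmed sets are used, for consistency with the
  trimmed/weighted chain of estimates.

## The mirror LI

The volume is flipped across the midsagittal plane and subtracted from
itself, giving one left-minus-right difference per homologous voxel pair
inside the ROI; voxels whose homolog falls outside the mask are dropped and
counted per side. No threshold is applied, so asymmetric *deactivation*
(both sides negative, one more so) contributes exactly like asymmetric
activation — the qualitative blind spot of suprathreshold methods, and the
reason the two fMRI estimators can disagree on deactivating regions.

To keep spatial autocorrelation between sampled voxels low, the difference
map is summarised by 1,000 independent subsets, each a random 5% of pairs
drawn without replacement; the estimate is the mean of the 1,000 subset
means and the CI their 2.5th/97.5th percentiles. The 5% fraction follows
the published pilot calibration and is exposed as configuration, not
re-derived. Subsets are drawn independently of one another (mutually
exclusive subsets would cap the count at 20). Note the estimate is a mean
*difference in t units*, not a bounded proportional LI; dividing by a
display constant (2.7 in the source study: the largest absolute difference
in their sample) maps it near [−1, 1] without affecting ranks or
categories.

Exact properties enforced by tests: flipping the input negates the estimate
and swaps the CI bounds when the same seed is used (the subsets are drawn
by pair id); adding a constant to every voxel changes nothing; scaling all
differences by k scales estimate and CI by k.

## The fTCD interaction LI

Preprocessing follows the standard fTCD chain, in an enforced order:
downsample 100 → 25 Hz (decimation; marker indices floored onto the new
grid); flag samples outside the per-channel 0.0001–0.9999 empirical
quantile band; normalise each channel to percent of its own mean (computed
over unflagged samples); heart-cycle integration (cardiac peaks on the
summed channels, minimum separation 60/150 s; every sample in a cycle
replaced by that channel's cycle mean); epoch from −12 s to 30 s around
each trial marker; reject trials containing normalised signal below 60% or
above 140% of the channel mean; baseline-correct each trial and side by
the mean of the −10 to 0 s window (the post-condition — baseline mean
exactly zero — is asserted per trial).

Two deliberate departures from a literal reading of the published chain:

* the published upper trial-rejection bound of 100% would reject virtually
  every pulsatile trial, since normalised signal routinely exceeds its own
  mean; it is presumed a misprint, 140% is the default and the literal
  value remains selectable (`reject_trials(high_pct = 100)`);
* the quantile flags are computed after downsampling, matching the listed
  stage order; the artefact *policy* is configurable — the default rejects
  any epoch overlapping a flagged sample, the alternative interpolates
  flagged samples linearly. With clean data the empirical quantile band
  flags ~0.02% of samples, so the flag-epoch policy sacrifices a material
  fraction of clean trials; simulation studies in the test suite use the
  interpolation policy for that reason.

A participant is excluded when strictly more than 20% of trials are
rejected (`floor(0.2 n)` rejected trials allowed; one more excludes —
3 of 15 at the default).

The LI is then the side × POI interaction of an additive model fitted to
the long-format kept epochs: a cubic B-spline smooth over epoch time
(default 10 df) absorbing the shared response shape, side and POI-boxcar
main effects, a categorical per-epoch effect, and the interaction, whose
coefficient is the percentage blood-flow difference between left and right
specific to the period of interest (positive = left dominant). The fit is
ordinary least squares with conventional Wald intervals (li ± 1.96 se):
the LI is a parametric coefficient and the smooth exists only to absorb
the shared shape, so penalisation is unnecessary; an independent penalised
fit (mgcv) is used as a cross-check in the tests and agrees on the
coefficient. POI windows are task parameters, not universal constants: the
defaults, 7–17 s for generation tasks and 7–27 s for matching tasks, are
conventions and should be set per protocol. Dividing by 6 for display
(`scale_li`) mirrors the source study's scaling and changes no category or
rank.

**Duplicated samples and standard errors.** After heart-cycle integration
every sample within a cycle is identical. Fitting at sample level would
count each cycle ~21 times and understate the SE by ~√21; the model is
therefore fitted on one observation per (epoch, side, cycle,
POI-membership) group. When epochs are constructed outside the pipeline
(no cycle ids), the fit uses every sample.

**Calibration and its limits.** On epochs with a flat shared response and
independent noise, the interval achieves its nominal 95% coverage, and an
injected interaction δ is recovered unbiasedly — both verified by
simulation in the test suite (200 and 100 seeds respectively). Through the
*full* pipeline two second-order effects appear, and are properties of the
method, not removed: cycle integration smears the δ boxcar at the POI
boundaries, attenuating the estimate by roughly the cycle length divided
by the POI length (≈5–10% at a 10 s POI); and residual pulsatility left by
cycle-boundary jitter is shared between the two channels, so it inflates
the residual SD without adding variance to the side-contrast coefficient —
the full-pipeline Wald interval is therefore conservative. Sign recovery
at δ = 6% is unaffected (≥95% over 100 seeded datasets is asserted).

## Classification and agreement

`categorise()` implements the CI rule (bounds exactly at zero count as
including zero — consistent with "zero included in the interval");
`spearman_with_ci()` computes the rank correlation with average ranks for
ties and a case-resampling percentile bootstrap CI (1,999 resamples by
default — an odd count gives unambiguous percentile indices; the published
analyses cite bootstrap CIs without parameters, so percentile is
implemented and labelled); `agreement_report()` assembles the correlation,
a 3 × 3 category cross-tabulation and the per-method percentage bilateral.

## What the synthetic data emulates — and what it does not

`synth_tmap()` places spherical bilateral blobs with per-side amplitudes on
a 32³ grid of 2 mm voxels (a desk-scale stand-in for a standard 2 mm
template grid; centres pair exactly across x = 0 and none sits on the
midline), adds optional Gaussian smoothing (separable convolution applied
to the blob pattern before noise) and voxelwise Gaussian noise. It
reproduces the features the estimators care about — amplitude asymmetry,
deactivation (negative amplitudes), threshold-dependent laterality — but
not the spatial autocorrelation, anatomical geometry or template asymmetry
of real maps (real 2 mm templates leave ~0.5–0.9% of voxels without a
homolog; the generator's grids are perfectly symmetric, so homolog dropping
is exercised by hand-built masks in the tests instead).

`synth_cohort_tmaps()` freezes a 30-subject cohort in the regime where the
two fMRI methods disagree in the documented direction: a broad weak
left-biased activation (base 2, gap ~ N(0.8, 0.3)) plus a small
contralateral high-t core (extra right amplitude ~ N(4, 0.5), radius 4 mm),
noise SD 1. The core makes the suprathreshold LI drift and reverse sign
toward the top of the threshold grid — the behaviour real maps show when
laterality is threshold-dependent — so the threshold-weighted histogram
spans zero (wide CI, bilateral call) while the mirror mean difference
remains decisively positive. With a *homogeneous* weak blob the contrast
inverts: the toolbox CI is then narrow because per-threshold LIs barely
drift. Passing the cohort contrast therefore shows the methods behave as
described in the threshold-reversal regime; it does not show that regime's
prevalence in real cohorts.

`synth_cbfv()` builds a pulsatile bilateral recording: a raised-cosine
pulse train at 70 bpm around per-channel base velocities of 60/55 cm/s
(typical adult middle-cerebral-artery values), a shared task response of
5% with 4 s raised-cosine ramps (haemodynamic transitions are gradual; a
square-edged response would leave lack-of-fit the spline cannot absorb), a
lateralised left-channel offset δ (default 6%) over the POI, Gaussian
noise, and optional injected spike artefacts. Trials follow the 5 s cue /
20 s task / 25 s rest structure, 23 trials by default. All additive
contributions are demeaned so each channel's mean equals its base exactly,
making normalised units recover δ without scale bias. Not emulated: heart
rate variability, respiratory oscillations, probe drift, and velocity
envelope asymmetries — so passing tests demonstrate algorithmic
correctness, not robustness to every physiological nuisance.

All generators are pure functions of their parameters and seed, and their
truth records (amplitude gaps, δ, spike locations) are what the downstream
tests assert against.

## Numerical choices and degenerate inputs

* RNG: every stochastic operation takes an integer seed, consumes one
  documented stream (left draws before right; ascending threshold order)
  and restores the caller's RNG state, so runs are bit-reproducible.
* Percentiles of unweighted bootstrap distributions use R's default
  (type 7) quantile; the weighted histogram uses the right-continuous
  weighted ECDF inverse defined above.
* Subset and resample sizes round half away from zero with a floor of 1.
* A zero LI denominator (L + R = 0) is a named error at the formula level;
  it cannot occur at positive thresholds, and an all-zero level fails the
  voxel gate instead.
* A constant recording passes heart-cycle integration unchanged (the
  integral of a constant is the identity for any boundaries); a
  non-constant signal with no detectable cardiac peaks raises an error
  suggesting a rate-band override rather than silently flattening data.
* Constant vectors make the rank correlation undefined and raise a named
  error rather than returning NA.

## Problem sizes used in validation

The simulation-based checks run at desk scale, chosen to exercise every
code path with comfortable statistical margins: 32³ volumes, a 30-subject
cohort, 8-trial recordings generated at 25 Hz for the 100-seed sign
recovery study, 6-trial constructed epochs for the 200-seed coverage
study, and 23-trial recordings where the protocol length itself matters.

## Known limitations

* The toolbox implementation follows the published description, not the
  source MATLAB code; bit-compatibility with that toolbox is a non-goal,
  and two of its under-specified choices (sum vs mean, trimmed vs untrimmed
  pooling) are configuration rather than fact.
* The mirror method assumes the template midline truly is the longitudinal
  fissure; nonlinear within-subject left-right alignment is out of scope.
* The fTCD interaction model claims equivalence to published generalised
  additive approaches only at the level of the interaction-coefficient
  contract, not basis-for-basis.
* Full-pipeline fTCD intervals are conservative and full-pipeline δ
  recovery is mildly attenuated, as quantified above.

## A worked example

```{r example, eval = FALSE}
syn <- synth_tmap(blobs = list(blob(c(-20, 0, 0), 12, 4, 1)),
                  noise_sd = 0.5, seed = 1)
mask <- exclude_midline(syn$masks[[1]], 5)
li_mirror(syn$volume, mask, seed = 1)
li_toolbox(syn$volume, mask, seed = 1)

rec <- synth_cbfv(n_trials = 23, delta = 6, seed = 1)
ep <- ftcd_preprocess(rec$recording, artefact_policy = "interpolate")
li_ftcd(ep, poi = c(7, 17))
```
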