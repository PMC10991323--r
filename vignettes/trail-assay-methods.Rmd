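---
title: "Methods: quantifying trail following from video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying trail following from video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anttrail)
```

`anttrail` measures how strongly a single ant follows a line drawn on a
rectangular paper arena, the standard behavioural readout when screening
candidate trail-pheromone compounds. This vignette explains the models and
procedures behind each stage, the parameters that matter, and the choices
made where the design was genuinely open.

## Coordinate conventions and calibration

Arena coordinates are millimetres with the origin at the arena's top-left
corner, x rightward and y downward, matching image row/column order. A
full-resolution pixel centre at (row r, col c), 1-based, maps to
((c − 0.5)/ppm, (r − 0.5)/ppm) with ppm = `px_per_mm`; after spatial binning
by a factor s the binned pixel pitch is s/ppm. The rendered frame covers
exactly the configured arena rectangle. A real camera's field of view
usually extends beyond the paper sheet, and the original recordings' exact
calibration is not recoverable from the frame size alone, so `px_per_mm` is
a required configuration input rather than a constant.

## Video compression

Recordings are binned 4 × 4 in space and 4 × in time before tracking; at
25 frames/s this gives a 160 ms frame period and, at typical calibrations,
roughly 1 mm binned pixels. Three design points:

* **Bin statistic: arithmetic mean**, not sum, so the intensity scale (and
  hence the segmentation threshold) does not depend on the binning factors.
* **Floor semantics**: trailing rows, columns or frames that do not fill a
  bin are dropped, avoiding partially weighted bins. The binned frame count
  is `floor(n / temporal_factor)`.
* Binning by a then b equals binning by ab when the factors divide evenly,
  which the test-suite asserts.

Temporal binning averages the ant over 4 consecutive frames; the blob in a
binned frame therefore represents the ant's mean position within the 160 ms
window, and all ground-truth position comparisons use the per-bin mean of
the true trajectory.

## Tracking

**Background.** Per-pixel temporal median over the stack (subsampled to
~100 evenly spaced frames in long recordings). With one moving ant, every
pixel is ant-free in well over half of the frames, so the median recovers
the static scene, including the trail line — which consequently cancels in
the difference image and needs no special handling during segmentation.
An optional line mask (`line_mask_halfwidth_mm`) exists as a safety net for
setups where the line's appearance changes when solution is applied.

**Segmentation.** The difference image d = background − frame is
thresholded at `threshold_offset` (default 0.15 on the [0, 1] grayscale;
the rendered ant sits ~0.7 below background, so the default tolerates
substantial contrast loss and is binning-invariant because the bin
statistic is a mean). Foreground pixels are grouped by 8-connected
component labelling; components with area outside
`[min_area_px, max_area_px]` are discarded; the largest surviving
component is taken to be the ant, ties broken by the larger summed
difference intensity (deterministic). Its d-weighted centroid, a sub-pixel
estimate, is the body-centre position. No surviving candidate marks the
frame invalid.

**Trajectory assembly.** Interior runs of at most `max_gap_frames`
(default 3 binned frames ≈ 0.5 s) invalid detections are bridged by linear
interpolation and flagged `interpolated`; longer runs stay invalid and
contribute no walked distance, and leading/trailing gaps are never filled.
The analysis window starts at the first valid detection — the moment the
ant enters the arena — and covers at most the configured duration.

## Trail metrics

The distance from each sample to the trail is the Euclidean distance to
the *closed* segment (endpoint-capped), since the applied trail is finite.
A valid sample is **on-trail** when that distance is strictly below
5 mm — equality is off-trail. The response variable y is the sum of step
lengths over steps whose **both** endpoints are on-trail; this conservative
attribution never credits a step that merely crosses the 10 mm band
(`rule = "either"` selects the permissive alternative). Path length sums
steps between consecutive valid samples only; a step across an invalid
sample contributes nothing. Occupancy heatmaps count valid samples into
2 mm cells (a compromise between display granularity and the binned pixel
pitch); edge-landing samples go to the higher-index cell; counts divided by
their total give the displayed passage probability.

Whether the original analysis summed displacements over on-trail samples
or measured progress along the line is not documented; y is implemented as
summed displacements, which also bounds it by the total path length.

## Statistics

Distances are transformed to Y = ln(y + 1) before any parametric test; the
transform handles the zero-inflated, right-skewed distances and maps y = 0
to Y = 0. The battery is:

* **One-way ANOVA** across all preparation × concentration groups
  (classical decomposition; 13 balanced groups of 15 give F on (12, 182)
  df, 18 groups give (17, 252)).
* **Dunnett's two-sided many-to-one comparisons** of every group against
  the control, using the pooled within-group variance on N − k df. The
  adjusted p-value of statistic t is P(max_j |T_j| ≥ |t|) under the
  multivariate t with the product correlation ρ_jk = b_j b_k,
  b_j = √(n_j/(n_j + n_0)). Conditioning on the shared control variate and
  the pooled scale factorises the joint probability into a two-dimensional
  integral, evaluated with 48-point Gauss–Legendre quadrature in each
  dimension. This is deterministic, accurate to ~10⁻⁵ (cross-checked
  against `mvtnorm` and `multcomp` in the tests), and fast enough to run
  thousands of Monte-Carlo calibration replicates. With a single
  comparison it reduces exactly to the pooled two-sample t-test.
* **Unpaired t-tests** between compounds at matched concentrations; the
  classic pooled-variance form by default, Welch as an option.

Both controls of a typical assay (solvent-only and untreated) can be kept
as groups in the ANOVA, with the untreated group as the Dunnett reference.
Star codes: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001, `****`
p < 0.0001.

## The synthetic-data generator

No public recordings exist for this assay, so the package generates its
own ground truth at every level.

**Locomotion model.** A correlated random walk sampled at the frame rate:
per step, the heading gains wrapped-normal noise with
SD 1/√`turn_concentration` rad, then turns by the fraction
`trail_attraction` of the angular gap toward a pursuit target on the trail
— the nearest trail point advanced 5 mm along the line in the direction of
travel. Pursuit steering was chosen over steering at the nearest point
itself: the latter makes a strongly attracted walker cross the line every
step, a sawtooth no finite-rate measurement can follow, whereas real
trail-following ants run along the trail. Walls reflect specularly; the
walk starts at the midpoint of the left short wall (where the entry tube
meets the arena) heading inward. Defaults — 20 mm/s while moving,
turn SD 0.2 rad/step, 5 % pause probability — are modelling assumptions
documented here, not measurements of any species' locomotion. At zero
attraction the walk explores the arena approximately uniformly, so its
on-trail occupancy converges to the trail band's area fraction (asserted in
the tests); occupancy grows monotonically with `trail_attraction`.

**Renderer.** One grayscale frame per sample: uniform background (0.85),
the trail drawn as a grey anti-aliased band (0.55, half-width 1 mm — the
printed line), the ant as a dark anti-aliased ellipse (0.15, 5 mm long,
aspect 0.4) aligned with its heading, optional additive Gaussian noise.
The smooth symmetric edge profile makes the blob's intensity-weighted
centroid match the true position to well under half a pixel, which the
tests verify by exhaustive pixel summation.

**Group-distance simulator.** For design-level questions the per-ant y
values are drawn directly: ln(y + 1) normal with mean
`control_mean_ln` + shift(group) and common SD `dispersion`, so the
statistics stage's assumptions hold by construction (y is clamped at 0; at
the default control mean of 3 ln-units the clamp is hit with probability
< 10⁻⁴). The defaults encode the study conditions: n = 15 ants per group,
a 13-group concentration ladder (two compounds × five concentrations, a
gland-extract positive control, solvent and untreated controls), and
`dispersion = 0.6` ln-units — chosen a priori by power analysis so that a
1.5 ln-unit shift at n = 15 is a clearly detectable effect (standardised
effect 2.5; joint Dunnett power across seven shifted groups above 90 %),
matching the qualitative pattern of strong significance above a
concentration threshold that such assays show. A `nonresponder_prob`
removes ants that never leave the entry tube, mirroring the assay's
2-minute exclusion rule.

**What the generator does not emulate:** real gait and body articulation,
antennation, pheromone evaporation during the trial, illumination
gradients and shadows, compression artefacts of camera codecs, or
multi-ant scenes. Passing tests therefore demonstrate the correctness of
the measurement chain on a compliant scene, not robustness to every field
condition; the noise-robustness tests (additive noise at SD 0.05) cover
only sensor-like noise.

## Numerical choices and degenerate inputs

* Point-to-segment distance is the closed-form projection with clamped
  parameter; degenerate (zero-length) segments are rejected at
  construction.
* On-trail threshold comparisons are strict (`<`), as is the area filter's
  inclusive range.
* ANOVA on responses with (numerically) zero within-group variance raises
  a dedicated degenerate-variance error instead of returning a meaningless
  F.
* Quadrature: 48 Gauss–Legendre nodes per dimension; the pooled-scale
  integral spans the 10⁻¹⁰ … 1 − 10⁻¹⁰ quantile range of √(χ²_ν/ν).
* Seeds: the simulators save and restore the global RNG state, so
  generating fixtures does not perturb a caller's random sequence.
* All reference checks in the test-suite use problem sizes chosen for
  desk-scale runs: 10 tracked ants of 60 s at 2 px/mm for the recovery
  property, 2000 replicates for null calibration, 400 for effect
  recovery.

## Known limitations

* Single-animal scenes only; no identity handling.
* No lens-distortion or perspective correction; calibration is a single
  isotropic scale.
* Frame input is PNG/TIFF sequences; standard video containers should be
  decomposed to frames externally (e.g. with ffmpeg) before analysis.
* The statistics stage assumes one observation per ant; colony of origin
  is carried as metadata only and not modelled as a random effect.
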