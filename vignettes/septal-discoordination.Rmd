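---
title: "Quantifying septal discoordination from speckle-tracking echocardiography"
author: "septostrain authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying septal discoordination from speckle-tracking echocardiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(septostrain)
```

## The problem

In dyssynchronous heart failure — typically left bundle branch block
(LBBB) — the inter-ventricular septum contracts early, is then stretched
by the delayed free wall, and so wastes part of its work. On a curve of
septal longitudinal strain over systole this appears as *systolic rebound
stretch*: positive strain excursions interrupting shortening. Three
indices summarise one cycle:

* **SS** (systolic shortening): the absolute sum of all negative strain
  increments between mitral valve closure (MVC) and aortic valve closure
  (AVC) — effective work;
* **SRSsept** (systolic rebound stretch): the sum of positive increments
  that occur *after shortening has begun* — wasted work. Stretch before
  the first shortening (pre-shortening stretch) is excluded by
  definition;
* **SDI** = SRSsept / SS: the septal discoordination index. Exercise
  raises blood pressure and depresses all strain amplitudes roughly
  proportionally, so only the ratio is comparable across loading
  conditions; the package reports all three but labels only SDI
  cross-intensity comparable.

Exercise testing is where heart-failure symptoms live, but it degrades
echo image quality and makes exercise Doppler (for valve timing)
impractical. The package therefore implements the full measurement chain
— septal meshing, block-matching speckle tracking, a least-squares strain
estimator, heart-rate-scaled valve timing, the index decomposition, and
the agreement statistics used to judge test–retest and observer
reproducibility — together with a synthetic ultrasound generator that
provides ground truth for every stage.

## Segment decomposition

`segment_systole()` groups consecutive samples of the systolic window
into runs by the sign of the first difference; zero increments merge into
the preceding run. The systolic window is the closed interval
`[MVC, AVC]` (the sample at AVC belongs to systole, matching the
convention that strain curves begin at MVC). A telescoping identity ties
the pieces to the net systolic strain change and is tested to 1e-9:

SS − (SRSsept + pre-shortening stretch) = −(strain(AVC) − strain(MVC)).

`ejection_frame_count()`, by contrast, counts frame samples in the
*half-open* window `[MVC, AVC)`, so that an ejection of exactly *n* frame
intervals counts *n* frames; a window of 0.34 s at 90 Hz holds 31
samples. The two conventions are deliberate and documented with each
function.

The phrase "directly after premature termination of shortening" is
operationalised as "after the first shortening segment has begun". The
alternative (count all systolic stretch) is reachable by summing the
flagged pre-shortening segments, which every decomposition reports. A
`noise_floor` argument (default 0 — the literal definition) lets a
sensitivity analysis suppress micro-oscillations.

## Valve timing at exercise heart rates

Systolic and diastolic durations vary non-linearly with heart rate.
`fit_phase_duration_splines()` fits smoothing splines (GCV-selected
smoothness by default, `spar` overridable) to a reference table of
systolic/diastolic durations versus heart rate; `scale_timing()` carries
a resting MVC/AVC annotation to an exercise heart rate by scaling the
resting systolic duration with the ratio of fitted systolic times, and
sets the cycle length from the exercise heart rate. Evaluation outside
the table's range clamps to the endpoints with a warning rather than
extrapolating.

The packaged default table is generated from the classic linear
regression of total electromechanical systole on heart rate (Weissler:
QS2 ≈ 0.546 − 0.0021·HR seconds, men), which has the two properties the
procedure relies on: absolute systolic time falls, and systolic *fraction*
rises, with heart rate. Any user table with columns
`hr_bpm, systolic_s, diastolic_s` — e.g. stress-specific reference values
— can be substituted; phase-specific tables (stress vs. recovery) are
supported by fitting one model per table.

## Synthetic cine-loops with known strain

The generator exists so that every downstream stage can be tested without
patient data; it emulates the acquisition conditions of a submaximal
exercise-echo protocol (zoomed septal views, 800 × 600 px, 50–90 Hz,
higher heart rate and worse image quality at higher intensity).

**Strain curves.** `generate_strain_curve()` places knots on the frame
grid and joins them with monotone cubic Hermite segments (Fritsch–Carlson
slopes, zeroed at direction changes). Because knots sit on sample times
and each inter-knot segment is monotone, the sampled curve's sign-run
decomposition reproduces the pattern's SS/SRS targets essentially exactly
(tested to 0.05 % strain); the seed jitters knot timing and the depth of
the first shortening without touching the targets. `stats::splinefun`'s
`monoH.FC` was not used because it does not zero slopes at
direction-change knots and overshoots there, which corrupts the targets.

**Geometry and deformation.** The septum is modelled as an annular band
segment (centre below the image, radius 560 px, half-span 0.32 rad,
thickness 56 px at full scale). Deformation applies a longitudinal
stretch ratio λ(t) = 1 + strain/100 along each radial layer's own arc
about the band mid-point, with thickness scaled by 1/λ
(incompressibility). Every layer then carries exactly the prescribed
longitudinal strain, so the mesh-averaged ground truth equals the input
curve, and `accumulate_strain()` applied to the exact trajectories
returns it to within 0.1 % strain (the residue is the chord/projection
error of a curved band).

**Speckle.** About 2000 point scatterers with uniform random amplitudes
are advected through the deformation and convolved with an isotropic
Gaussian point-spread function (σ = 2 px) — no wave simulation.
Degradation is additive Gaussian noise (images clipped at zero) and, for
a configurable fraction of frames, a randomly placed occlusion disc
zeroing part of the septum, standing in for shadowing and out-of-plane
motion. What this generator does *not* emulate: anisotropic PSFs and
depth-dependent resolution, reverberation and side-lobe artefacts,
through-plane speckle decorrelation, probe motion. Passing tests
therefore demonstrate correctness of the measurement chain under
idealised speckle, not clinical-grade robustness.

**Cohorts.** `simulate_cohort()` gives each subject a base pattern
(LBBB-type with SS ~ U(10, 18) %, SRS ~ U(2, 6) %, or non-LBBB with zero
SRS; LBBB prevalence 0.44 by default, matching a dyssynchronous HF
cohort) and two visits whose parameters are the base plus independent
zero-mean noise of SD `visit_noise_sd` — so paired visit differences have
SD √2 × `visit_noise_sd`. Observer readings add independent noise of SD
`observer_noise_sd` (observer 1 twice, for intra-observer agreement, and
observer 2 once). Heart rates per intensity are drawn around the medians
60 / 79 / 90 / 97 / 78 bpm (rest, 30/60/90 % VT, recovery) with IQR-scaled
jitter, and each loop's noise level gets lognormal acoustic-window jitter
around its intensity's median. Exercise modulates discoordination
heterogeneously: each subject draws a response factor on the log-SDI
scale (SD 0.5) that scales the rebound target with a per-intensity
exercise weight (0 / 0.6 / 1.0 / 1.3 / 0.5 from rest to recovery), while
shortening is mildly depressed with intensity (afterload); the factor is
a subject property shared by both visits, so consistent improvement,
consistent worsening and reciprocal ΔSDI responses all occur in a
cohort, in proportions of the same order as a dyssynchronous HF group.
All randomness flows through explicit seeds.

## Tracking

`build_mesh()` lays an 11 × 31 grid over the segmentation polygon: the
medial axis is approximated by slicing along the principal axis; if the
centerline deviates from its chord by more than 2 % of its length the
band is treated as curved, a circle is fitted to the centerline (Kasa
fit, iterated once on the radially re-sliced midline to remove chord
bias) and stations are placed by angle. Each point carries a local
longitudinal (tangent) and radial unit vector and its initial arc-length
coordinate. The approach assumes the band is function-like along its
principal axis, which holds for septal segments up to roughly a third of
a circle; it is not a general medial-axis transform.

`estimate_displacements()` matches a block (default 21 px) around each
point between consecutive frames by exhaustive normalised
cross-correlation over the search window (default radius 10 px), refined
to sub-pixel by a separable parabolic fit of the peak — on
log-correlations when positive, since the NCC peak of Gaussian-PSF
speckle is near-Gaussian. Matches with peak correlation below 0.4, or
whose block leaves the image, are flagged invalid and in-filled with the
median of valid grid neighbours, never silently zeroed.

Two standard regularisations suppress drift, which would otherwise grow
roughly linearly with time because each point's local speckle realisation
induces a small persistent bias: forward–backward symmetric matching, and
5 × 5 box smoothing of each frame pair's displacement field over the mesh
grid with windows shrunk *symmetrically* at the band edges (an asymmetric
window biases the smoothed field, and hence strain, toward interior
values). The true inter-frame field is nearly affine, so the smoothing
does not distort it. Both are exposed and can be disabled.

`accumulate_strain()` projects each point's cumulative displacement onto
its initial longitudinal direction and takes the least-squares slope of
that projection against the initial arc-length coordinate over a sliding
kernel of 7 stations (shrunk at the ends); the curve is the mean over the
mesh, in percent, zero at the reference frame. No drift compensation is
applied across the cycle — cumulative strain is reported from the
initially segmented configuration, and on curved bands a rigid image
shift couples into apparent strain through tangent rotation (≈
offset/radius), so residual end-of-cycle strain serves as a drift
diagnostic rather than being corrected.

With the defaults, noise-free full-scale loops track with trajectory RMSE
below 0.5 px and strain RMSE well below 1 % strain; SS and SRS are
recovered within ±1.5 % strain over the study's index range (SS 8–20 %,
SRS 0–6 %). These are the figures the acceptance tests assert.

## Quality grading and exclusion

`grade_quality()` scores four components on [0, 1]: septum/background
intensity contrast, structure definition (in-band versus background
gradient energy), image-plane stability (global frame-to-frame shift),
and artefact burden (fraction of invalid matches). The grade thresholds
the composite mean — good at ≥ 0.92, poor below 0.84 by default. The
thresholds were calibrated once against the generator's degradation
scale: noise-free loops grade good, heavily noisy loops (noise ≈ 0.7)
grade poor without being excluded. Exclusion is separate and mirrors the
"incomplete view of the septum" rule: a loop is excluded when any frame
pair loses more than 30 % of its mesh points, which occlusion discs
trigger reliably while diffuse noise does not.

## Agreement statistics

`bland_altman()` (bias, SD of differences, bias ± 1.96 SD),
`paired_ttest()` (a guard around `stats::t.test` that refuses
zero-variance differences), `curve_similarity()` (down-samples the longer
curve by linear interpolation, normalises each by peak |strain|, returns
Pearson r — the normalisation affects reported curves, not r),
`cohen_kappa()` (marginal-product chance correction) and
`icc_absolute_single()` — ICC(A,1), the two-way model for absolute
agreement of single measurements, computed from the ANOVA mean squares
with the standard F-based confidence interval. Tests pin the point
estimate and interval to an independent two-way ANOVA decomposition and
to an externally computed reference value. Missing pairs are dropped
listwise with a logged count; incomplete ICC matrices are an error, never
imputed. For ΔSDI response agreement, "no change" is dichotomised as
worsening (conservative); the cut is a flag, not a constant.

## Pipeline and reproducibility

`run_pipeline()` chains cohort simulation, (optionally) loop synthesis
and tracking, quality exclusion, indices and the agreement battery into a
`study_report` whose provenance block records the seed and an md5 hash of
the configuration; identical configurations produce byte-identical
reports. `analyze_existing()` applies the tracking half to user-supplied
loops (PNG stack + JSON sidecar, or a lossless RDS container; the PNG
path is 8-bit quantised and documented as such).

## Problem sizes and numerical choices

The packaged analyses and tests use: 20 full-scale loops for strain
recovery; 1000 random piecewise-linear curves against a brute-force
sign-run oracle; 200 simulated cohorts of 50 subjects for the √2
test–retest law; 500 replicates of a 200 × 2 two-way table for ICC
recovery; 12 seeds × 4 dropout levels for the exclusion-monotonicity
check, with image-based checks run at a proportionally scaled desk
geometry (260 × 200 px, radius 190 px) whose tracking accuracy was
verified to match the full-scale setting. Ties in the correlation search
resolve to the first maximum in row-major window order; block centres
round to the nearest pixel; sub-pixel offsets are clamped to ±0.5 px.

## Known limitations

2-D longitudinal strain only; no radial/circumferential components and no
3-D motion. Segmentation is an input (the study design has two observers
segmenting manually) — no automatic septum detection. The degradation
model is parameterised, not asserted: real exercise noise sources (probe
pressure, respiration) are not quantified in the source setting. The
timing reference is a configurable stand-in for stress-specific
reference data, and scaled AVC inherits that table's error. Pressure–
strain work indices are out of scope (no blood-pressure data).
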