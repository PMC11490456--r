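---
title: "Measuring facial soft tissue depths: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring facial soft tissue depths: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fstdkit)
```

## The problem

Forensic facial approximation rebuilds a face over an unidentified skull by
applying population-specific facial soft tissue depths (FSTDs): the
bone-to-skin distance at anatomically defined cranial landmarks, in
millimetres. Building such a dataset from head CT scans involves a chain of
steps, each with its own error sources: segmenting skull and skin surfaces
from the intensity volume, orienting the skull in a standard frame, placing
landmarks, measuring horizontal bone-to-skin distances, quantifying observer
error, and summarising the cohort by age and sex. `fstdkit` implements this
chain end to end, together with the statistics used to compare a new cohort
against published reference populations.

Because raw CT data cannot be redistributed, the package also ships a
synthetic-data module that produces voxel phantoms with *analytically known*
depths and cohort tables with known statistical structure. Every stage of
the pipeline can therefore be validated against ground truth.

## The landmark registry and the measurement frame

Depths are taken at a registry of 23 cranial landmarks
(`landmark_registry()`): 5 mid-sagittal (supraglabella, glabella, nasion,
mid-nasal, rhinion) and 17 bilateral, giving 39 measured positions; the
nasomaxillofrontale is located only as an aid for placing the
mid-nasomaxillare and carries no depth, because eyelids obstruct the
corresponding skin point.

Before measurement the skull is posed in the Frankfurt Horizontal Plane
(FHP), the plane through both porions and both orbitales. Four points
over-determine a plane, so `fit_fhp()` fits a total-least-squares plane and
reports the RMS point-to-plane distance as `fit_residual`; the classical
three-point convention (both porions plus the left orbitale) is available
via `method = "three_point"`. The frame's conventions are fixed and all
directions are expressed in them: +x anterior (from the mean porion towards
the mean orbitale), +y towards the subject's left (right porion to left
porion), +z superior. With only four approximately coplanar points a
left/right porion swap is not detectable from geometry alone — it flips the
frame upside down — so `fit_fhp()` accepts an optional `superior_hint`
point (any point known to lie above the plane, e.g. bregma) and warns when
that hint maps below the plane.

## Segmentation

Skin and skull surfaces are segmented by intensity thresholding.
`histogram_thresholds()` computes the class boundaries by maximising the
between-class variance of the intensity histogram (multi-level Otsu), the
standard formalisation of valley-seeking histogram segmentation; for a
three-class head volume this yields the air/soft-tissue and
soft-tissue/bone thresholds. When several placements tie (an empty valley),
the midmost placement is returned. Both thresholds can be overridden
manually in `segment_volume()`, mirroring interactive edge correction.

`extract_surface()` meshes the threshold iso-surface with a
marching-tetrahedra scheme (six tetrahedra per cell sharing a body
diagonal, linear interpolation along edges), which is watertight on closed
phantoms and places vertices sub-voxel on the level crossing. Two defaults
matter:

* **Field pre-smoothing** (`presmooth_sigma = 1` voxel). On a near-binary
  label field, midpoint-interpolated iso-surfaces acquire a staircase
  texture that inflates areas and Hausdorff distances. A light Gaussian
  smoothing of the *intensity field* turns the class step into a ramp whose
  half-maximum crossing sits on the true boundary, so the iso-surface
  localises the tissue interface at sub-voxel accuracy (on a noiseless
  sphere phantom the extracted area is within 0.1% of the analytic value,
  against several percent without smoothing). This is field-level
  smoothing for boundary localisation; **no mesh-level smoothing is ever
  applied**, and `presmooth_sigma = 0` disables it.
* **Largest connected component only**, both for the voxel mask and the
  mesh: isolated noise blobs (the analogue of scanner-table artefacts) are
  discarded. A mask touching the grid border cannot produce a closed
  surface; the result is flagged `closed = FALSE` (or an error with
  `on_open = "error"`).

Partial-volume voxels are assigned by threshold only; an optional radius-1
binary closing (`closing = TRUE`) is available but off by default.

## Depth measurement

The cephalometric (skin) landmark is defined by tracing the cranial
landmark to the skin and measuring the *horizontal* distance. The package
formalises the trace as a single ray cast from the cranial point along a
horizontal measurement direction, taking the first intersection with the
skin mesh (`measure_depth()`); the first-hit rule is what motivates
excluding landmarks whose trace is obstructed (the nasomaxillofrontale).

The direction depends on the landmark's measurement plane
(`measurement_direction()`):

| plane            | direction                                            |
|------------------|------------------------------------------------------|
| sagittal         | +x (anterior)                                        |
| coronal          | laterally outward: +y on the left, −y on the right   |
| sagitto-coronal  | outward surface normal projected onto z = 0, renormalised |

The per-landmark plane assignment is a documented convention of this
package (mid-sagittal landmarks sagittal; strongly lateral landmarks —
frontotemporale, frontomalare temporale, ectoconchion, mid-zygomatic,
jugale, zygion, condylion — coronal; the remaining bilateral landmarks
sagitto-coronal), overridable per call via the `planes` argument of
`measure_subject()`: the three planes are standard but no published
per-landmark assignment exists to transcribe. Surface normals are
area-weighted averages of incident triangle normals, which is stable on
coarse meshes; when a projected normal is nearly vertical (|projection| <
1e-6) the direction falls back to the bisector of the anterior/lateral
quadrant of the raw normal and the record is flagged.

Every reported direction has |z| ≤ 1e-9, depths are invariant under rigid
motions of the whole scene to 1e-6 mm, and landmarks that cannot be
measured (outside the skin, ray through a hole, unmeasured registry
entries) are reported as missing with a reason — never imputed.

## Precision and observer error

Re-segmentation precision is quantified by the Hausdorff distance between
surface pairs. `hausdorff()` reports both directed distances (maximum over
sampled points of one surface of the point-to-*triangle* distance to the
other) and the symmetric distance as their maximum, since published
practice is ambiguous about directedness. Sampling is area-weighted uniform
over triangles plus all vertices (so sharp features are always covered) and
seeded; doubling the sample count moves phantom estimates by well under
5%. A symmetric distance above 0.5 mm classifies the re-segmentation as
poor.

Observer error uses the anthropometric standards:

* TEM = √(ΣD²/2N) over N remeasured pairs with session differences D;
* rTEM = 100·TEM/VAV, with VAV the mean of the two session means; values
  at or below 5% are flagged reliable (5.0% itself counts as repeatable);
* R = 1 − TEM²/S², accurate between 0.8 and 1, unreliable below 0 (reported,
  never clamped).

For S² the package defaults to the pooled sample variance of all
measurements, the standard definition in the anthropometric error
literature; a literal "squared mean session difference" mode
(`s2_mode = "mean_difference"`) is exposed for comparison but degenerates
whenever TEM is close to the mean difference, and typical published R
ranges (0.8–1) are only consistent with the variance convention.

## Cohort statistics

Ages are binned into 18–34, 35–44, 45–54, 55–64 and ≥65 years.
`descriptive_table()` summarises n/mean/SD/min/max per landmark position ×
sex × age group, with missing landmarks reducing n.

Test selection is a pure function of a Shapiro–Wilk screen at α = 0.05 on
the analysis variable (the depths for group tests, the paired differences
for asymmetry): parametric when p ≥ 0.05, otherwise the rank-based
counterpart. `age_sex_effects()` runs, per landmark position, a two-factor
between-subjects analysis (type-III sums of squares with sum-to-zero
contrasts, the convention of mainstream social-science ANOVA output) and
lays the age, sex and interaction p-values out one row per factor; a
genuinely multivariate variant across landmarks (Pillai trace on complete
profiles) is available behind `mode = "multivariate"`. The per-landmark
layout is the default because published effect tables print one p-value
per landmark and factor.

`bilateral_asymmetry()` tests per-subject left-minus-right differences
(paired t or Wilcoxon signed-rank by the normality gate) and reports the
absolute mean difference alongside. All location tests carry a seeded
bootstrap p (`bootstrap_p()`): nonparametric case resampling at the subject
level of null-shifted data, with the two-sided p taken as the proportion of
resampled t statistics at least as extreme as the observed one (with a +1
continuity correction). A percentile-t resampling scheme was chosen because
it is the standard default when a bootstrap is specified only by its
resample count; 1000 resamples is the default.

## Population comparison

Reference mean-depth tables for six populations (Greek, Cretan, Turkish,
Korean, Czech, French) are packaged as plain-text fixtures, exactly as
printed in the comparison tables of the Greek FSTD study. Three choices
follow from treating the printed tables as the source of truth:

* each table keeps its own granularity — most pool left/right into a single
  value, the Czech table keeps sides separate — and the loader preserves
  that rather than harmonising; Greek means are therefore loaded *per
  comparison* (`load_reference("greek", "M", versus = "cretan")`);
* differences are computed at printed precision (2 decimals, rounding half
  away from zero) so that published extreme differences are reproduced
  exactly rather than approximately;
* comparing two summary tables yields differences only — one-sample tests
  (`one_sample_tests()`) require the raw per-subject cohort, and the French
  reference exists only pooled across sexes.

`interpopulation_extremes()` recomputes the eleven published extreme
mean-difference statements from the fixtures alone.

## The synthetic-data module

`make_phantom_volume()` builds a star-shaped "skull" (default an ellipsoid)
wrapped in a soft-tissue shell whose *radial* thickness is a known function
of direction, voxelised by containment into air/soft-tissue/bone
intensities with optional Gaussian noise. Defining thickness along rays
from the skull centroid is what makes the ground truth closed-form for any
star-shaped profile. The phantom emulates the features the pipeline relies
on — three intensity classes, closed nested surfaces, known depths — and
deliberately not realistic cranial anatomy, partial-volume blur from a
scanner point-spread function, or Hounsfield calibration; passing phantom
tests validates the geometry and numerics of the pipeline, not its
performance on clinical data.

`simulate_cohort()` draws depth tables with the structure the analysis
assumes: per-landmark, per-sex normal depths (truncated at zero by
*redrawing*, not clipping, to preserve approximate normality), balanced
sex × age-group cells, an optional left-minus-right shift at bilateral
landmarks, an optional linear age slope, and two measurement sessions with
independent Gaussian session noise. Defaults are chosen to resemble a real
FSTD study: landmark means and SDs default to the pooled per-sex values of
the packaged Greek descriptive tables, five age groups mirror the cohort
bins, and the default session noise of 0.3 mm sits mid-range of published
intra-observer TEMs (roughly 0.1–1 mm). Depths are simulated independently
across landmarks; real faces correlate neighbouring landmarks, but no
published per-landmark covariance exists to transcribe, so parameter
recovery tests should be read per landmark, not jointly.

## Numerical choices and problem sizes

* Histogram thresholds use 128 bins and mid-plateau tie-breaking.
* Ray hits closer than 1e-9 mm are treated as the origin itself; points
  within 1e-3 mm of the skin count as on it. The inside/outside parity
  probe uses a direction oblique to the voxel lattice, with coincident
  shared-edge hits collapsed, so landmarks lying exactly on lattice planes
  are classified robustly.
* Analytic ground-truth meshes are subdivided icospheres (level 4 by
  default, ~5k vertices); radial rays through mesh vertices intersect the
  nested surface exactly at a vertex, which is what makes 1e-6 mm depth
  checks meaningful on faceted meshes.
* The validation suite uses a 115³-voxel sphere phantom (50 mm skull, 5 mm
  shell, 1 mm voxels) for the end-to-end depth-recovery check and 1000-rep
  null simulations at 40 subjects for calibration of the two-factor,
  paired-asymmetry and one-sample tests; these sizes give sub-voxel depth
  errors and ±1.5% calibration resolution while keeping the whole suite in
  the order of a minute.

## Known limitations

* Landmark *placement* is an input: the package measures depths at given
  cranial points but does not locate Sg, G, N … on a mesh automatically —
  automated landmarking would be a new method needing its own validation.
* Only the upper-skull registry is covered; mandibular and lower-face
  landmarks are out of scope, as are curved/geodesic depth definitions.
* Printed reference tables cannot support recomputing their significance
  columns (that requires the underlying raw cohorts); the packaged p-values
  are integrity surfaces, not reproduction targets.
* BMI is absent from the cohort model, as body composition data is not part
  of the depth-table schema.
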