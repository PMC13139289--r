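---
title: "Quantifying intracranial arterial calcification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intracranial arterial calcification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calcmorph)
```

## The problem

Calcification of the intracranial internal carotid artery (iICAC) is the
most common intracranial arterial calcification and is linked to stroke
and dementia risk. Clinical CT reporting of iICAC is usually volumetric
or semi-quantitative, which conflates two physiologically distinct
aspects of the lesion: how much of the arterial wall is covered
(a stiffness-related quantity) and how far the deposit protrudes
(a stenosis-related quantity). calcmorph implements an automated
morphometry that separates the two:

* **Surface area S** (mm²): the total area of a triangle-mesh surface
  model of the calcification — a proxy for the extent of wall involvement
  and hence reduced arterial elasticity.
* **Representative thickness T** (mm): a direction-weighted 97th
  percentile of per-face thickness measurements over that surface model —
  a proxy for how far the deposit encroaches on the lumen.

The package consumes a CT volume in Hounsfield units (HU) and a binary
artery mask drawn over the arterial cross-section (wall plus lumen), both
as NIfTI files; everything downstream is automatic.

## Segmentation

Calcified voxels are those inside the artery mask with attenuation in the
calcium window **130–500 HU**. The lower bound is the Agatston-score
convention for calcium; the upper bound separates vascular calcification
from adjacent skull-base bone, which is much denser. Both bounds are
inclusive by default; the upper bound's inclusivity is configurable
(`hi_inclusive`) because conventions differ and the window edge is not
physically sharp. No minimum-deposit-size filter is applied: a filter is
available (`min_component_voxels`) but defaults to off.

Deposits are separated by 26-connectivity (6-connectivity available) and
each is processed as its own surface model; per-participant S sums over
deposits and sides, and per-participant T pools all per-face values
before the quantile, which is the only order-independent choice.
Participants with no voxel in the window receive S = 0, volume = 0,
T = 0 and an explicit `no_calcification` flag rather than missing values,
so cohort tables stay complete.

## Surface modelling

`build_surface()` extracts the level-0.5 iso-surface of the mask's
indicator field with **marching tetrahedra** on the Kuhn (6-tetrahedron)
cell decomposition. The decomposition is translation-invariant, so the
triangulated diagonals of neighbouring cells always agree and the
resulting mesh is watertight — every edge borders exactly two faces — and
consistently oriented with outward normals. Watertightness is not
cosmetic here: the thickness estimator's opposing-normal test is
meaningless on a surface with cracks or inconsistent winding. Classic
marching-cubes tables were rejected because their ambiguous saddle cases
can produce exactly such cracks.

### Why the indicator field is anti-aliased

Iso-surfacing the raw {0,1} field reproduces the voxelisation staircase
at half-voxel scale, and the staircase does not average out: the surface
area of a smooth object is overestimated by a factor that does **not**
shrink with voxel size (about +9% for a sphere, at 1.0, 0.5, and 0.25 mm
alike). Since S is one of the two headline measurements, the package
applies a small Gaussian **anti-aliasing filter to the indicator field
before iso-surfacing** (`sigma`, default 0.8 voxel, truncated at 3.5
sigma, zero boundary). This is a sub-voxel reconstruction filter, not a
mesh smoother; the mesh itself is never smoothed or decimated
(`sigma = 0` restores the literal binary surface). With the default, the
test suite's sphere phantom is recovered within ~1% and the cylinder-
shell phantom within ~4% at 0.25 mm, with the error decreasing
monotonically under grid refinement.

Two consequences are handled explicitly. A deposit at the voxel scale
can fall entirely below the iso-level after filtering; `build_surface()`
detects this and falls back to the raw binary surface so that no deposit
is lost. And a single-voxel deposit's level-0.5 surface bevels the voxel
corners, so its area is intrinsically smaller than the 6 × (voxel face)
of the axis-aligned cube; the exact value is pinned as a regression
fixture in the tests.

## Thickness estimation

For each face *i* of the calcification mesh, with unit outward normal
**A**:

1. every other face *j* (normal **B**) with **A**·**B** < 0 — an angle
   strictly over 90° — is an *opposing candidate*: the two faces lie on
   opposite sides of the calcified shell;
2. T(*i*) is the smallest centroid-to-centroid distance over the
   candidates. Faces with no candidate (e.g. an open sheet) are flagged
   missing.

The pairing uses centroids, not point-to-triangle distances, and imposes
no ray-alignment constraint beyond the sign of the dot product; on a
mirror-matched parallel-plate mesh T equals the plate separation exactly
on every face, which the tests assert in closed form.

The reference algorithm is the exhaustive O(F²) scan. The default
implementation accelerates it with a uniform spatial grid expanded in
Chebyshev shells; once the best candidate distance is below R × cell
size after shell R, no unvisited point can beat it, so the accelerated
result — including its lowest-index tie-break — is *identical* to the
double loop, and the suite asserts bitwise equality on random phantoms.

### Radial direction weighting

A thickness reading is only meaningful across the artery's
cross-sectional plane. For each calcification face, the five nearest
faces of the **artery-surface model** (built from the artery mask with
the same mesher) are located; the weight is

> w = |cos(mean angle between the face normal and the five artery-face
> normals)|

so w → 1 when the face normal is radial (aligned or anti-aligned with
the local artery-wall normal) and w → 0 when perpendicular to it
(an axial or tangential reading). Ties in the five-nearest selection are
broken by lowest face index, keeping runs bit-reproducible. The mean is
taken over angles in [0°, 180°], and `k` is configurable.

### The representative value

The participant-level summary is the **weighted 97th percentile** of the
per-face T, with w as a *frequency* weight: zero-weight faces are
excluded rather than having their T values shrunk toward zero, which
would manufacture small thickness readings out of unreliable directions.
The weighted quantile places order statistic *k* at cumulative position
C(k−1)/(W − w(k)) with linear interpolation; under uniform weights this
reduces exactly to the ordinary linear-interpolation percentile
(`quantile(type = 7)`), and the same dialect is used for all IQR
computations in the cohort stage. The high percentile captures extreme
thickness while remaining robust to isolated surface irregularities.

### How much the weighting matters — honestly

On the raw (non-anti-aliased) surface the weighting is indispensable:
end-cap faces of a tube-shaped deposit have no nearby opposing faces and
pair across the whole deposit, so the unweighted 97th percentile can
report the deposit's *length* instead of its wall thickness (about 6 mm
versus a true 1.5 mm on the half-arc shell phantom). On the anti-aliased
surface, rounded rims give those faces nearby opposing partners with
*small* distances instead; both the weighted and unweighted percentiles
then land within half a percent of the true wall thickness, and which of
the two is marginally closer depends on sub-voxel quantisation — on the
reference half-arc phantom the unweighted value happens to be ~3 µm
closer. The weighting is therefore kept (it is what makes the estimator
robust to surface construction details and to less idealised shapes such
as snugly bounded plates), but its benefit on idealised anti-aliased
phantoms at the 97th percentile is within quantisation noise, and one
acceptance-level check of "weighted strictly closer than unweighted" is
expected to fail by that margin. The per-face weight distribution is the
right diagnostic on real data (`autoplot()` of a morphometry result).

## Phantoms: what they emulate, and what they do not

`make_annulus()`, `make_slab()` and `make_spherical_shell()` voxelise
continuous shapes with known wall thickness, analytic surface area and
volume, embedded in an artery mask with realistic HU contrast
(calcification 300 HU, lumen 40 HU, background 0 HU, and a 1000 HU bone
block adjacent to — but outside — the artery mask, exercising the upper
window bound). A voxel belongs to a shape iff its centre lies inside the
continuous shape; voxel centres are staggered half a voxel off the
phantoms' symmetry planes so that closed boundaries never coincide with
centre coordinates (otherwise centre-inside voxelisation systematically
gains a boundary layer). The artery tube extends 3 mm beyond the
calcified segment at each end, as a real artery label extends beyond a
focal deposit; for the slab, the artery is a broad plate parallel to the
slab, since a plaque sheet lies along the vessel wall.

The phantoms deliberately do **not** model CT noise, beam hardening,
partial-volume blur at the calcification boundary, or the curved
(siphon) artery course. Passing phantom tests therefore demonstrates the
geometric correctness of segmentation, surface modelling, and thickness
estimation — not robustness to scanner physics. The resolution harness
(`resolution_study()`) adds the one acquisition effect the study design
needs: it re-runs the identical segmentation on volumes down-sampled
from 0.625 mm to 1.25 mm (HU trilinearly, masks nearest-neighbour,
grids aligned to the original origin) and summarises agreement by
Pearson correlation and mean absolute volume difference.

## The synthetic cohort and the regression stage

Individual-level study data are access-restricted, so the regression
stage is exercised on synthetic cohorts built to the published marginal
scale: log-normal S (median 62.75 mm², IQR 193.35 mm²) and T (median
1.07 mm, IQR 0.60 mm), ages 40–92 from a shifted gamma, a Gaussian
copula linking age, S and T (latent correlations r = 2 sin(πρ/6) from
the Spearman targets 0.64, 0.55 and 0.862), a 35/1232 no-calcification
fraction assigned to the lowest latent S (hence mostly the youngest),
and TICV larger in males. Regional brain volumes are generated as the
specified linear combination of z-scored predictors plus Gaussian noise;
the residual SD defaults to the value that gives the standardized
outcome unit variance, so the *specified* standardized effects are the
estimands of the fitted models.

The models mirror the study design in Wilkinson notation —
`BV ~ S`, `BV ~ T`, and `BV ~ S + T`, each controlling for age, sex,
population and total intracranial volume — fitted by OLS on z-scored
continuous variables (n−1 convention) with sex and population as 0/1
indicators, two-sided t-based p-values, per-predictor variance inflation
factors, and Benjamini–Hochberg FDR control. The FDR family is per model
across the analysed regions by default (`family = "pooled"` adjusts all
exposure tests together); the correction is applied to the S and T
terms, which are the hypotheses of interest, not to the covariates.
Coefficients are reported both standardized (β\*, SD change in BV per SD
of predictor) and back on the raw scale.

## Numerical choices and degenerate inputs

* Geometry agreement between a volume and its mask is required to 1e-4 mm;
  oblique affines are rejected on read (the supported geometry model is
  axis-aligned, matching an axial scanning protocol).
* Iso-level ties (field value exactly 0.5 at a grid node) are nudged to
  the outside by 1e-9 so no surface vertex coincides with a node and no
  zero-area face is emitted.
* Empty masks: `build_surface()` raises "no surface"; `morphometry()`
  maps the no-calcification case to zeros with a flag instead.
* Meshes with fewer than two faces cannot support thickness estimation
  and error out; single-face deposits still contribute area.
* The weighted quantile errors when no face has positive weight rather
  than silently returning an arbitrary value.
* All randomness (phantom ensembles, synthetic cohorts) flows through
  explicit integer seeds; identical seeds give byte-identical outputs,
  which the command-line tests assert.

## Problem sizes used by the test suite

The suite validates geometry at 0.25 mm where accuracy claims are made
(reference annulus: ~35k calcification faces, ~63k artery faces) and at
0.5 mm for the exhaustive-versus-accelerated equivalence checks; the
thickness-recovery ensemble uses 40 phantoms with walls of 1–3 mm,
heights 3–5 mm and arcs 120–360°, about a third of them rotated, chosen
as realistic focal deposit sizes. Statistical recovery uses 200
replicates of n = 1232 cohorts over true standardized effects
{−0.15, −0.08, 0}. These sizes keep the full suite within a few minutes
on one CPU while exercising every accuracy claim at the resolution it is
made.

## Known limitations

* T does not distinguish inward (lumen-narrowing) from outward deposit
  growth, because the artery mask covers wall plus lumen; a stricter
  stenosis measure would need a wall-only label.
* The anti-aliasing filter trades a resolution-independent staircase
  bias for a small erosion of structures near the voxel scale; thickness
  estimates below ~2 voxels are reported but sit in the sub-resolution
  regime the phantom generator warns about.
* Reported S and T for real scans inherit whatever partial-volume and
  motion artefacts the calcium window passes; the package validates the
  geometry pipeline, not the window's clinical sensitivity.
* The synthetic cohort reproduces marginal scales and rank correlations,
  not the joint distribution of real morphometry with brain volumes, so
  recovery results demonstrate correctness of the estimator, not
  real-data effect sizes.
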