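# calcmorph

Automated morphometry of intracranial internal carotid artery
calcification (iICAC) from CT, for imaging researchers studying the
vascular contribution to brain ageing. Given a head CT in Hounsfield
units and a binary artery mask (the manually labelled arterial
cross-section, wall plus lumen), calcmorph segments the calcification,
builds a watertight triangle-mesh surface model of each deposit, and
reports two scalar measurements per participant, together with the
statistical machinery used to relate them to regional brain volumes.

## The measurements

**Segmentation.** Voxels inside the artery mask with attenuation in the
calcium window 130–500 HU are calcified: the lower bound is the
Agatston-score convention, the upper bound excludes adjacent bone.

**Surface area `S` (mm²)** — a proxy for arterial stiffness — is the sum
of triangle areas over the surface model,

    S = Σ_f area(f),

with the surface extracted at iso-level 0.5 of the (anti-aliased) mask
indicator by marching tetrahedra, so the mesh is closed and consistently
outward-oriented.

**Thickness `T` (mm)** — a proxy for stenosis — is measured per face:
for face *i* with unit normal **A**, every face *j* whose normal **B**
satisfies **A**·**B** < 0 (normals more than 90° apart, i.e. the
opposite side of the shell) is a pairing candidate, and

    T(i) = min_j || centroid(i) − centroid(j) ||.

Each reading is weighted by its alignment with the local artery wall:
with θ̄ the mean angle between the face normal and the normals of the
five nearest artery-surface faces, the weight is `w = |cos θ̄|` (1 for a
radial measurement across the vessel cross-section, 0 for an axial or
tangential one). The participant-level value is the weighted 97th
percentile of T over all faces — extreme thickness, robust to local
surface irregularities.

The cohort stage fits, per brain region, the standardized linear models
`BV ~ S`, `BV ~ T`, and `BV ~ S + T`, each controlling for age, sex,
population, and total intracranial volume, with variance inflation
factors and Benjamini–Hochberg FDR control across regions.

Because clinical CT and artery labels cannot be redistributed, the
package ships voxel phantom generators with analytic ground truth
(cylindrical shells, slabs, spherical shells, with realistic HU contrast
including adjacent bone) and a synthetic cohort generator matched to the
published marginal scales, so every stage is testable end to end.

## Worked example

```r
library(calcmorph)

# a cylindrical-shell deposit, 1.5 mm wall, inside an artery tube
spec <- phantom_spec(shape = "annulus", r1 = 2, r2 = 3.5, height = 6,
                     arc = 360, spacing = 0.25)
ph <- make_annulus(spec)
result <- morphometry(ph$ct, ph$artery)
print(result)
#> <morphometry_result>
#> # A tibble: 1 × 7
#>   id          side   S_mm2 T_rep_mm volume_mm3 n_components no_calcification
#>   <chr>       <chr>  <dbl>    <dbl>      <dbl>        <int> <lgl>
#> 1 participant pooled  250.     1.52        153            1 FALSE
```

The shell's analytic surface area is 259.2 mm² and its true wall
thickness 1.5 mm: the mesh recovers `S` within ~4% at this voxel size
and the representative thickness within a tenth of a voxel (1.52 mm at
0.25 mm spacing). `autoplot(result)` shows the weighted per-face
thickness histogram behind the 97th-percentile line.

```r
cohort <- synthesize_cohort(synthetic_cohort_spec(
  n = 1232,
  regions = tibble::tibble(region = c("subcortical", "occipital"),
                           beta_S = c(-0.14, 0), beta_T = c(0, 0)),
  seed = 11))
fits <- fit_bv_models(cohort, c("subcortical", "occipital"), models = c(1, 3))
dplyr::filter(fits, term %in% c("S_mm2", "T_mm"))
#>   model region      term  beta_std se_std  p_value         p_adj   vif
#> 1     1 subcortical S_mm2  -0.136  0.0221 8.67e-10 0.00000000173  1.18
#> 2     1 occipital   S_mm2  -0.0358 0.0241 1.37e- 1 0.137          1.18
#> 3     3 subcortical S_mm2  -0.130  0.0243 1.07e- 7 0.000000428    1.43
#> 4     3 subcortical T_mm   -0.0176 0.0278 5.26e- 1 0.526          1.87
#> 5     3 occipital   S_mm2  -0.0175 0.0265 5.09e- 1 0.526          1.43
#> 6     3 occipital   T_mm   -0.0499 0.0302 9.94e- 2 0.199          1.87
```

The generating model gave the synthetic subcortical volume a true
standardized S effect of −0.14 and the occipital volume none; the fits
recover −0.136 (FDR-significant) and −0.036 (not significant), with all
VIFs below 2. `tidy()` and `glance()` work on single fits, and
`autoplot(fits)` draws the coefficient dot-and-whisker panel.

A command-line wrapper with subcommands `segment`, `surface`,
`morphometry`, `phantom`, `synth-cohort`, and `analyze` is installed at
`system.file("cli", "calcmorph", package = "calcmorph")`; see
`?cli_run`.

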