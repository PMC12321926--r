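# neonasal

Automated 3-D CT morphometry of the neonatal nasal airway.

Congenital nasal pyriform aperture stenosis (CNPAS) narrows the bony
anterior opening of a newborn's nasal cavity; because neonates are obligate
nasal breathers this causes respiratory distress and sometimes requires
surgical dilation. Diagnosis uses CT, conventionally a single manual
measurement of the pyriform aperture width (stenosis: width < 11 mm) — a
2-D proxy that misses how far the narrowing extends along the cavity.
`neonasal` implements a fully automatic 3-D analysis for clinicians and
imaging researchers working with neonatal head CT:

* **Segmentation** of the nasal air column: volume-of-interest selection,
  virtual nostril-closure lines isolating nasal from external air, a global
  −400 HU threshold with small-object (< 2 mm³), external-air and
  oropharynx removal, adaptive local thresholding of the −400…−125 HU
  partial-volume band (a voxel joins when its HU is below the mean of its
  3×3 neighbours at or above −400 HU and it is 3-D connected to the initial
  mask), and connectivity filtering that flags anatomically isolated
  regions such as a completely obstructed nostril.
* **Landmarks**: the pyriform-aperture plane (most anterior coronal slice
  with ≥ +200 HU bone at the nasal-tip level) and the choanae plane (first
  slice, scanning posterior→anterior, where the main cavity's width drops
  by ≥ 1.5×, marking the division into two passages).
* **Morphometry**: minimum width in the lower aperture with the strict
  `width < 11 mm` stenosis flag; nares / mid-nasal / nasopharynx / total
  volumes (cm³, total = exact sum); iso-surface (marching-tetrahedra)
  surface area (cm²); combined cross-sectional-area profiles (mm²) on
  percent-of-length axes with ±5 % station averages at 0/25/50/75/100 % of
  the mid-nasal axis.
* **Statistics**: Dice and sensitivity against reference masks, and
  two-sided Mann–Whitney U contrasts (exact for small untied samples)
  between normal, moderate and severe groups.
* **Phantoms**: a parametric CT-like head phantom with two nasal passages,
  configurable aperture gap, bone ring, choanae width step, noise and
  partial-volume blur — with exact analytic ground truth (volumes, width,
  areas, landmark planes), so the whole pipeline is testable without
  clinical data.

Inputs are DICOM series or NIfTI volumes in Hounsfield units; any
axis-aligned orientation is reordered into a canonical anatomical frame.

## Worked example

```r
library(neonasal)

# a stenotic phantom at CT-like resolution (0.5 x 0.3 x 0.3 mm),
# 20 HU noise, 0.4 mm partial-volume blur
ph <- generate_phantom(phantom_spec(aperture_gap = 4.7,
                                    noise_sd = 20, blur_sd = 0.4, seed = 1))
case <- run_case(ph$volume, case_id = "demo")
case
#> <nasal_case> demo
#> <morphometry_report> demo
#>   pyriform width 5.1 mm  [stenosis suspected: < 11 mm]
#>   volumes (cm^3): nares 0.503, mid-nasal 2.194, nasopharynx 1.619, total 4.316
#>   surface area 23.56 cm^2
```

The designed 4.7 mm gap is measured as 5.1 mm under 20 HU noise and
0.4 mm blur (on noise-free scans it is recovered to the in-plane voxel)
and correctly flagged as stenotic; the volumes are the voxel volumes of
the three regions delimited by the detected pyriform and choanae planes,
and their sum is the total by construction. Against the phantom's exact
truth mask this segmentation scores

```r
m <- segment_airway(ph$volume)
dice(main_mask(m), ph$truth$mask)
#> [1] 0.9078941
sensitivity(main_mask(m), ph$truth$mask)
#> [1] 0.999136
```

— near-perfect sensitivity, with the Dice value reflecting that the
adaptive stage deliberately includes the partial-volume shell around the
sharp geometric boundary (see the methods vignette for the quantitative
analysis). A cohort run mirrors the published group comparison:

```r
specs <- cohort_specs(seed = 1)   # 12 normal / 4 moderate / 6 severe
vols <- setNames(lapply(specs$spec, function(s) generate_phantom(s)$volume),
                 specs$case_id)
cohort <- run_cohort(vols, groups = specs[, c("case_id", "group")])
tidy(cohort)[, c("parameter", "mean_moderate", "mean_severe", "p_c")]
plot_group_profiles(cohort)
```

with the mid-nasal volume and the 75 % station area separating severe from
moderate cases while the pyriform width does not — the pattern that makes
posterior 3-D measurements useful for surgical decisions.

A thin command-line front end (`inst/cli/neonasal.R`) exposes
`phantom | segment | measure | validate | compare | run-case | run-cohort`
for shell use.

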