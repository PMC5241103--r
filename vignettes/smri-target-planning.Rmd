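---
title: "Methods: sMRI-guided radiotherapy target planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sMRI-guided radiotherapy target planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrirt)
```

## The problem and the pipeline

Glioblastoma is an infiltrative tumor: conventional radiotherapy targets
built from contrast-enhanced T1 (enhancement + resection cavity → GTV2)
and FLAIR (edema/abnormality → GTV1) miss microscopic disease. Whole-brain
spectroscopic MRI measures the Cho/NAA ratio — elevated where proliferative
non-neuronal cells replace neurons — on a coarse grid (nominal
4.4 × 4.4 × 5.6 mm voxels), which can be standardized and merged into the
planning targets. The pipeline implemented here is:

1. **Ratio and upsampling.** Cho/NAA is formed voxelwise on the
   spectroscopic grid (`ratio_map()`, with a denominator floor guard) and
   carried into the ~1 mm clinical grid by trilinear interpolation
   (`resample_trilinear()`).
2. **Fold-normalization.** The ratio map is divided by its mean over
   contralateral normal-appearing white matter (`segment_nawm()`,
   `normalize_fold()`), giving *fold-normal* units in which NAWM averages
   exactly 1; metabolite levels vary with age, sex and location, so an
   internal reference is required.
3. **Segmentation.** Voxels at or above a fold threshold (1.5, 1.75, 2.0
   by default) inside the brain form the metabolic abnormality
   (`threshold_segmentation()`).
4. **Target construction.** Conventional volumes expand GTVs by metric
   margins (CTV1 = GTV1 + 7 mm, CTV2 = GTV2 + 5 mm, clipped to brain;
   PTV = CTV + 3 mm, unclipped); the abnormality is merged by union into
   `sMRI_CTV2`/`sMRI_CTV1` and re-expanded to sMRI PTVs
   (`build_conventional()`, `build_smri()`).
5. **Dose and metrics.** A parametric conformal dose stands in for
   inverse planning (`generate_dose()`); plans are scored for volume
   change, Dice overlap, abnormality escaping the 51/60 Gy isodose
   regions, target coverage, brainstem maximum, and recurrence coverage
   (`evaluate_plan()`).
6. **Cohort statistics.** One-sided paired t, one-sample t against 1.0,
   and one-way ANOVA, implemented from closed forms (`cohort_stats()`).

All stages assume co-registered inputs on axis-aligned grids; registration
and spectral fitting are upstream of this package.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| CTV1 / CTV2 margins | 7 / 5 | mm | standard GBM practice: microscopic spread around FLAIR / enhancement |
| PTV margin | 3 | mm | setup uncertainty; not anatomically clipped |
| Fold thresholds | 1.5, 1.75, 2.0 | — | with an NAWM absolute ratio of ~0.6 these correspond to absolute Cho/NAA ≈ 0.9–1.2, the pathological range |
| Prescriptions | 51 (or 54) / 60 | Gy | PTV1 / PTV2 over 30 fractions, simultaneous integrated boost |
| Coverage goal | 95% (PTV2 floor 90%) | % | 100% of dose to 95% of target; relaxation near brainstem |
| Brainstem limits | soft < 54, hard < 60, ≤ 10% above 54 | Gy | point-maximum convention |
| NAWM `p_min` | 0.9 | probability | strict WM membership; configurable, logged |
| NAWM exclusion dilation | 10 | mm | keeps peritumoral signal out of the reference |
| NAWM minimum volume | 10 | cm³ | below this the reference is refused rather than diluted |
| Dose penumbra | 5 | mm | logistic falloff scale of the dose surrogate |

The NAWM probability cutoff, exclusion dilation and minimum size have no
canonical published values; the defaults above were fixed once as
clinically sensible and are explicit arguments, recorded in provenance.

## The synthetic phantom

No patient images ship with the package, so `generate_phantom()` produces
complete synthetic patients with known ground truth:

* an ellipsoidal brain (semi-axes 45% of the field of view) split into
  hemispheres at the midsagittal plane; white-matter probability high in a
  deep shell (35–75% of the ellipsoidal radius);
* a tumor with strictly nested cavity (8 mm) ⊂ enhancing core (15 mm) ⊂
  FLAIR abnormality (25 mm), radii typical of a post-resection
  glioblastoma;
* a continuous infiltration field `f(x) = A·exp(−d(x)²/σ²)`, with `d`
  the distance outside the core, `A = 2` and `σ = 12 mm` — infiltration
  extending one to two centimeters beyond enhancement, consistent with how
  metabolic abnormalities extend past the enhancing border;
* Cho/NAA = `baseline · (1 + f) · ε` sampled **on the coarse
  spectroscopic grid**, with Cho raised and NAA suppressed so their
  quotient equals this field exactly; `baseline = 0.6` absolute;
* multiplicative lognormal noise `ε` with CV 10% by default. No published
  noise model exists for these maps; this choice is the package's own
  (ratio data are positive and heteroscedastic) and is clearly labelled
  synthetic;
* a brainstem surrogate (central-inferior 8 mm ball) and a recurrence
  simulator: a connected blob of requested volume seeded with probability
  proportional to `mixing · f + (1 − mixing)` outside the core, so
  `mixing = 1` reproduces the observation that recurrence arises
  preferentially where pre-treatment Cho/NAA was elevated and
  `mixing = 0` is the uniform null.

Two-grid realism is deliberate: metabolite maps are *generated* coarse and
must travel the trilinear-upsampling path before thresholding, so
partial-volume behavior is exercised, not bypassed. What the phantom does
**not** emulate: susceptibility and lipid artifacts, irregular tumor
shapes, anatomical barriers other than the brain surface (falx,
tentorium), registration error, and realistic recurrence biology. Passing
tests therefore demonstrate geometric and statistical correctness of the
pipeline, not clinical performance on real data.

Cohorts (`run_cohort()`) randomize tumor side, location (±8 mm jitter),
radii (core 12–18 mm, FLAIR +8–14 mm, cavity 5–9 mm) and infiltration
length (9–15 mm) per patient, all from one master seed; reruns are
byte-identical.

## Numerical conventions

* **Coordinates.** Voxel indices are 0-based; world mm positions refer to
  voxel centers; one fixed right-handed, grid-aligned orientation is
  enforced on NIfTI load (flips and permutations normalized; oblique
  affines rejected).
* **Rasterization.** A voxel belongs to a contour iff its center is
  inside under the even–odd rule; nested polygons subtract. This matches
  how planning systems binarize and is exactly testable. Contour
  extraction traces the 0.5-level set per slice, so
  rasterize ∘ extract reproduces masks with Dice ≥ 0.99 at ≥ 3-voxel
  feature scale.
* **Margins.** `expand_margin()` thresholds an exact separable Euclidean
  distance transform honoring anisotropic spacing, with distances measured
  voxel-center to voxel-center — the definition an all-pairs brute-force
  oracle reproduces exactly. Voxelization makes the result slightly
  conservative: a lattice-centered 10 mm sphere expanded 3 mm on a 1 mm
  grid lands ~2.7% below the continuous 13 mm ball, and chaining two
  expansions (GTV→CTV→PTV) roughly doubles that deficit. This is an
  intrinsic property of sampled margins, shared by standard imaging
  toolchains; the box/region distance alternative was evaluated and
  rejected because voxel boxes bulge past the continuous surface
  (~+15% on the same sphere).
* **Thresholds and isodoses** use closed (≥) comparisons — the
  conservative, larger-target convention.
* **Normalization order.** The *ratio* is normalized by the NAWM mean
  ratio (rather than normalizing Cho and NAA separately and re-ratioing);
  the two differ in general and the text of standard protocols permits
  either. Ratio-first is the default because the segmentation thresholds
  are defined on the ratio; normalizing per-metabolite first can be
  composed manually from `normalize_fold()` applied to each map.
* **Order of operations.** The fold map is upsampled and *then*
  thresholded (upsampling precedes volume work in the clinical protocol);
  thresholding on the coarse grid first and upsampling the mask is
  possible by resampling a 0/1 map but is not the default.
* **Degenerate inputs.** Both-empty Dice is defined as 1.0 and logged;
  empty segmentations give (0 cm³, 0%) outside-volumes with a warning;
  zero-variance statistics raise errors naming the degeneracy rather than
  returning NaN; invalid voxels are an explicit companion mask, never
  sentinel values, so reference means exclude rather than dilute them.
* **Determinism.** Every stochastic step takes a seed; global RNG state is
  saved and restored around internal draws.

## Problem sizes

The default phantom is a reduced head — 120³ voxels at 1.5 mm — chosen so
a full single-patient pipeline runs in seconds; the spectroscopic grid is
always the nominal 4.4 × 4.4 × 5.6 mm. The test suite uses 48–60³ grids at
3–3.75 mm for cohort-level properties (50-phantom construction-invariant
sweeps, 20-cohort directional replication) and the reduced default for the
threshold-recovery check; the acceptance script uses 72³ at 2.5 mm with 5
patients. These sizes are the package's own trade-off between geometric
fidelity and iteration speed; all invariants they exercise are
size-independent.

## Known limitations

* Margin expansion is voxel-discrete (see above); sub-millimeter accuracy
  requires finer grids, not a different algorithm.
* The dose surrogate is conformal by construction: it always meets
  coverage inside targets and cannot represent beam-arrangement
  compromises, so organ-at-risk conflicts manifest only through geometric
  proximity.
* The recurrence simulator displaces recurrence further from the boost
  volume than typical clinical cohorts (its seed density follows the
  infiltration field directly), which makes conventional-coverage numbers
  lower than clinical experience; directional comparisons between plans
  remain meaningful.
* DICOM-RT transport is out of scope; structure sets use the documented
  JSON dialect, and NIfTI carries all volumes.
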