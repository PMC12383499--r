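---
title: "Tracking individual liver metastases between imaging timepoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking individual liver metastases between imaging timepoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepatrack)
```

## The problem

Patients with secondary liver tumors — for example neuroendocrine liver
metastases — are monitored with follow-up MRI, and the clinical response
call (progressive disease, stable disease, partial/complete response)
hinges on how individual lesions changed between two examinations.
Standard response criteria (RECIST 1.1) measure only a couple of target
lesions per organ because measuring every lesion by hand is impractical;
patients with dozens of metastases and mixed responses are exactly the
ones where a per-lesion view matters most. Given automatic segmentation
masks for the liver and for all lesions at both timepoints, the whole
per-lesion analysis can be automated. `hepatrack` implements that
automation: it consumes four binary NIfTI masks (lesions and liver at
baseline and follow-up) and produces a per-lesion differential growth
table, category calls, tumor loads, consistently relabelled label maps,
and category-coded overlay volumes. It deliberately stops short of a
patient-level diagnosis — that call stays with the radiologist.

## The procedure

The pipeline in `track_patient()` runs six conceptual steps.

**1. Lesion isolation.** Each binary lesion mask is decomposed into
connected components; each component is one metastasis and receives an
integer label (`label_components()`). The connectivity is configurable
(6/18/26); the default is 26, the most inclusive standard choice, which
also reproduces the clinically observed behaviour that two lesions
growing toward each other fuse into one component. Components whose
voxels are not majority-inside the liver mask (strictly more than 50%)
are discarded as extrahepatic false positives (`restrict_to_liver()`);
surviving lesions are kept whole rather than clipped, since clipping
would silently alter the volumes of boundary lesions.

**2. Geometry.** All volumes are reoriented to the canonical RAS
orientation at load, so "axial" is unambiguously the third voxel axis
regardless of how the scanner stored the data. The two timepoints may
have different grids and spacings (multi-scanner follow-up is the norm);
nothing assumes a shared grid.

**3. Registration.** The follow-up examination is aligned to the
baseline using only the two *liver* masks — organ-level alignment is
more anatomically relevant than whole-image registration and needs no
intensities. The transform is rigid (6 degrees of freedom). This is a
deliberate floor: growth is the measurand, and an affine or deformable
transform could absorb genuine growth into the registration.
`estimate_liver_registration()` initialises with centre-of-mass
alignment, estimates rotation by aligning the principal axes (second
moments) of the two masks, and refines translation with a deterministic
coarse-to-fine coordinate descent on a trilinearly smoothed liver-overlap
score. Two properties are guaranteed: the result is deterministic (no
random restarts), and the final liver Dice is never below the
centre-of-mass-only Dice. We estimate rotation from moments rather than
from overlap search because the voxelisation phase of a resampled mask
creates spurious overlap maxima a few degrees away from the truth; mask
moments are volume-weighted and do not suffer from this. On ellipsoid
phantoms the estimator recovers rotations up to 10 degrees within about
0.3 degrees and translations within half a voxel.

**4. Correspondence.** The follow-up label map is resampled onto the
baseline grid with nearest-neighbour interpolation (any other scheme
would invent labels), *only* to compute overlaps. For every pair of a
baseline lesion `i` and follow-up lesion `j` two scores are computed
(`pairwise_scores()`):

- Euclidean centroid distance `d(i, j) = ||c_i − c_j||` in mm, using
  exactly transformed native centroids, and
- Dice overlap `Dice(i, j) = 2 |V_i ∩ V_j| / (|V_i| + |V_j|)` of the
  voxel sets on the shared grid.

`match_lesions()` then assigns one-to-one matches in three deterministic
stages: overlap-first greedy (dice descending), then a distance-gated
greedy fallback (default gate 10 mm) for small or displaced lesions that
do not overlap after registration, then merge detection — an unmatched
baseline lesion that still overlaps an already-matched follow-up
component is flagged as *merged* into it. Whatever remains is *new*
(follow-up side) or *disappeared* (baseline side). Overlap outranks
distance because overlap is the stronger evidence; the distance gate
prevents pairing distant unrelated lesions. Greedy assignment with full
tie-breaking (dice, then distance, then label order) is used instead of
a globally optimal assignment because real instances are sparse — on
phantoms with up to 20 lesions, displacements up to 5 mm and growth
factors 0.5–1.5 the greedy matching equals the exhaustive optimum
(verified in tests against an enumeration oracle on small instances).
Merge detection is directional (baseline into follow-up), matching the
clinical definition; a split is represented as one match plus one new
lesion since no split category exists in the reporting scheme.

**5. Measurement.** Per-lesion size is quantified at each timepoint in
that timepoint's *native* space — registration and resampling never
touch a reported number. Volume is voxel count × voxel volume (cm³).
The largest axial diameter is the in-plane Feret distance between voxel
centres, maximised over axial slices (mm): for every slice containing
lesion voxels, the maximum pairwise distance of in-plane voxel centres
(computed on the convex hull, which is affine-invariant in index space).
Centre-to-centre distances underestimate the physical extent by up to
one in-plane voxel, but the estimator is deterministic and the
systematic half-voxel bias largely cancels in *relative* change, which
is what classification uses. A single-voxel lesion has diameter 0; a
relative change with a zero baseline denominator is reported missing
(such lesions fall under the measurability cut-off anyway).
`growth_table()` assembles volumes, diameters and their absolute and
relative differences per tracked lesion.

**6. Classification and reporting.** Each lesion track receives exactly
one category (`classify_growth()`), with precedence: new, merged,
disappeared (statuses outrank size rules), then *too small to measure*
(diameter below 5 mm at **both** timepoints), then progressive
(relative diameter change ≥ +20%), regressive (≤ −30%), else stable.
Both thresholds are closed ("at least"). A new lesion is always "new"
regardless of size, because the too-small rule requires both timepoints.
Disappearance is reported as its own category by default; a config flag
folds it into regressive for strict six-category reporting. Categories
are decided by diameters only — volume deltas are reported but never
classified on. `build_report()` orders the table the way a reader
triages it — new lesions first, then matched lesions by descending
relative diameter growth, then merged, then disappeared, ties by label —
and attaches tumor loads (sums of per-lesion volumes), per-category
counts, and the orange/blue colour code (orange iff progressive or new).
`write_category_volume()` exports label volumes recoded with small
integer category codes (`category_codes()`), keeping rendering a viewer
concern.

## Tunable parameters

| Key | Default | Meaning |
|---|---|---|
| `connectivity` | 26 | voxel adjacency for lesion isolation (6/18/26) |
| `registration.enabled` | `TRUE` | rigid liver-mask registration on/off |
| `registration.max_rotation_deg` | 15 | trust bound on the estimated rotation (deg) |
| `registration.translation_step_mm` | 1 | finest translation refinement step (mm) |
| `matching.max_distance_mm` | 10 | centroid-distance gate for overlap-free matches (mm) |
| `thresholds.progressive_pct` | 20 | minimum relative diameter increase (%) |
| `thresholds.regressive_pct` | 30 | minimum relative diameter decrease (%) |
| `thresholds.min_measurable_mm` | 5 | measurability cut-off (mm, both timepoints) |
| `thresholds.fold_disappeared_into_regressive` | `FALSE` | six-category strict reporting |
| `report.order_by` | `"diameter"` | growth ordering variable (`"volume"` optional) |

The three threshold values are the RECIST 1.1-derived constants; the
rest are implementation choices exposed deliberately
(`default_config_yaml()` prints them all, and the CLI accepts a YAML or
JSON config).

## The phantom generator

Because per-lesion ground truth does not exist for clinical data, the
package ships a deterministic phantom module. A `phantom_spec()`
describes an ellipsoidal liver and spherical lesions with scripted
radii, growth factors, per-lesion displacements, appearance and
disappearance events, and one global rigid motion applied to the whole
follow-up; `generate_phantom_pair()` rasterises both timepoints by
voxel-centre inclusion (matching the centre-based metrics) and returns
the masks together with the true transform, the true correspondence at
component level, analytic volumes/diameters and true categories.
Default grids use 1.5 × 1.5 × 2 mm voxels, a typical hepatobiliary-phase
resolution; the default liver is an adult-sized ellipsoid (semi-axes
55 × 42 × 45 mm). `phantom_scenario()` provides a fixed library: identity,
all-stable, mixed growth, merge (two lesions whose grown versions fuse),
new lesion, disappearance, a "solitary progression" case (one growing
lesion among five shrinking ones, so the tumor load falls while the
patient is progressive — the clinically treacherous constellation), and
a randomised 20-lesion cohort (radii 3–6 mm, growth factors 0.5–1.5,
displacements up to 5 mm, global motion 3° + a few mm) behind a single
seed.

What the phantoms do *not* emulate: segmentation errors, irregular
lesion shapes, partial-volume effects at mask boundaries, and
non-rigid deformation of the liver between visits. Passing the phantom
suite therefore demonstrates the correctness of the tracking logic and
metrology on clean inputs, not robustness to imperfect segmentations —
on clinical data the upstream segmentation quality bounds the tracking
quality.

## Numerical choices and edge cases

- Soft (probabilistic) masks are binarised at 0.5 on read; 0/1 masks
  pass through unchanged, and binarisation is idempotent.
- Label order is the deterministic first-voxel array scan order, so runs
  are bit-reproducible; all greedy stages break ties deterministically.
- Empty lesion masks at either or both timepoints are valid inputs
  (everything becomes new/disappeared; both empty gives an empty
  report). An empty liver mask degrades to identity registration with a
  warning instead of failing the run.
- Exactly 50% inside the liver counts as outside (the rule is strictly
  greater than half).
- Problem sizes in the test and acceptance suites: phantom grids of
  96×96×64 to 120×112×80 voxels, registration phantoms at 2 × 2 × 2.5 mm,
  sphere metrology at 1 mm spacing — small enough to run the whole suite
  in about a minute on one core while keeping rasterisation error well
  below the tolerances being tested.

## Known limitations

- Tracking covers exactly two timepoints; longitudinal chains of three
  or more visits must be tracked pairwise by the caller.
- Split events (one baseline lesion becoming two follow-up components)
  are reported as one match plus one new lesion; there is no split
  category in the reporting scheme.
- The 20% growth threshold is known to be aggressive for very small
  lesions, where one voxel of rasterisation noise can exceed it; the
  measurability cut-off absorbs the worst of this, but calls on lesions
  near 5 mm deserve visual review.
- Rigid registration cannot model breathing-related deformation of the
  liver; the matching stages tolerate the residual misalignment through
  the overlap-then-distance design, but extreme deformation would
  degrade correspondence.
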