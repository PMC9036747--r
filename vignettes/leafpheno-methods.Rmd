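---
title: "Methods: multi-component phenotyping of detached lettuce leaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-component phenotyping of detached lettuce leaves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafpheno)
```

## The measurement problem

A detached lettuce leaf is not one object but several functional regions:
the blade (BD, the whole leaf), the mid-rib (MR, the central vascular axis
made of the petiole plus the first-order vein), the second-order veins
(VS), and the laminas (LM, the flat photosynthetic panels bounded by veins,
mid-rib and margin).  Two further components follow by set algebra: the
venation `VV = MR | VS` and the marginal zone `MZ = BD & !VV & !LM`, the
band of blade along the edge that belongs to neither veins nor laminas.
Mechanical support and transport run through MR and VS; photosynthesis is
concentrated in LM; leaf color differs strongly between the adaxial
("positive") and abaxial ("back") faces.  Quantifying the components
separately — instead of the whole leaf only — yields traits (vein angles,
petiole length, per-component color, area ratios) that discriminate
cultivars far better than whole-leaf statistics.

`leafpheno` implements the measurement layer of such a pipeline.  Its
input is the set of per-component binary masks for one leaf plus the RGB
photograph; producing those masks (image segmentation) is deliberately out
of scope.  Its output is a 266-trait vector per leaf — 30 geometry, 20
venation and 216 color traits — plus cohort-level statistics.

## Normalization into the size-free space

Leaves are photographed at arbitrary orientation and differ greatly in
size, so every leaf is first mapped into a common "size-free" frame:

1. **Upright rotation.**  The minimum-area oriented bounding box of the
   mid-rib is cut across its long axis at the midline.  The half carrying
   the larger mid-rib pixel mass is the petiole half — the petiole stroke
   is always markedly wider than the first-order vein — and the line
   connecting the two halves' mid-rib centroids is rotated to the
   vertical, petiole down.  Should the two halves tie exactly, the lower
   half is taken as the petiole (leaves hang petiole-down at acquisition).
2. **Width scaling.**  The rotated leaf is scaled uniformly so the blade's
   horizontal extent is 500 px.  The scaling factor — original blade width
   over 500 — is itself a size trait.  The 500 px target balances spatial
   detail against processing cost; all downstream defaults (simplification
   tolerance, adjacency radius) are calibrated to this frame.
3. **Handedness flip.**  Back-face photographs are mirror images of the
   positive face; after normalization they are flipped about the vertical
   axis so both faces share handedness.  The criterion is the recorded
   acquisition orientation; the flip can be disabled.

Masks are resampled with nearest-neighbor interpolation (labels must not
blur), the photograph bilinearly.  "Width" here means the horizontal
extent of the upright blade: normalized leaves share their width and keep
their individual lengths.

Rotation invariance is the key quality check: normalizing rotated copies
of one leaf must give near-identical scaling factors.  Across 20 synthetic
leaves pre-rotated by 0-180 degrees in 30-degree steps, the per-leaf
standard deviation of the scaling factor stays below 0.03 (the acceptance
suite asserts this bound; `scripts/acceptance.R` recomputes it).

## Skeletons and the mid-rib axis

Vein networks are summarized by their skeletons.  Thinning uses the
Zhang–Suen parallel algorithm followed by a sequential simple-point
cleanup that removes the 2-px staircase "dominoes" Zhang–Suen leaves
behind, giving strictly unit-width, 8-connected skeletons.  Endpoints
(one skeleton neighbor) and branch points (three or more) describe the
network; skeleton length counts axial steps as 1 and diagonal steps as
sqrt(2), summed over a minimum spanning tree of the pixel-adjacency graph,
plus a per-endpoint compensation equal to the distance-transform value at
the tip — thinning retracts every free end by about the local stroke
radius, and without the compensation the skeleton of a 5 px thick band
under-measures its length by 8-9%.

The mid-rib axis — the arc-length coordinate every vein attachment is
referenced to — needs more care than a raw skeleton:

* The longest end-to-end skeleton path fixes the topology and the basal
  end; side spurs shorter than 20 px (thinning artifacts at the shoulders
  where the petiole stroke narrows) are pruned first.
* In the normalized pose the mid-rib is near-vertical, so the path is
  replaced by the row-wise mean column of the stroke: this centerline
  runs the full stroke extent (no tip retraction) and is immune to the
  chamfer-metric error — a pixel chain overestimates the length of an
  oblique curve by up to ~8% because it can only step in 8 directions.
  Degenerate end rows (corner slivers created by rotating the blunt
  petiole end) are trimmed by a pixel-count criterion.  For oblique
  mid-ribs the skeleton path is kept, tips extended along their tangents
  capped by the distance transform.
* Arc positions are read off a lightly smoothed copy of the path
  (moving-average; window 5 for the row-wise centerline, 17 for pixel
  chains).

These choices are validated against the generator's analytic centerline:
mid-rib length and every attachment arc must agree with ground truth to a
few pixels (see the acceptance suite's petiole bound below).

## The lamina-based vein architecture

Second-order vein angles are hard to measure on the vein skeleton itself
(junctions are noisy at stroke scale).  The lamina-based route uses the
panels between veins instead:

1. **First-order laminas.**  Lamina components that intersect the mid-rib
   dilated by the adjacency radius r = 5 px are "first-order" — directly
   attached to the mid-rib.  Components under 25 px² are dropped;
   fragments of that size are segmentation debris and the dominant source
   of count errors.
2. **Petiole.**  Each first-order lamina projects to the arc position of
   its nearest axis pixel (ties within 1 px resolved toward the base);
   the smallest arc s* over laminas splits the mid-rib: petiole below,
   first-order vein above, `PE_L = s*`, `AP_L = MR_L - s*`.
3. **Polygon simplification.**  Each lamina contour (Moore boundary
   trace) is simplified with Douglas–Peucker at tolerance 5 px — in the
   fixed 500 px frame one tolerance fits all leaves.  The simplified
   polygon's vertices are a subset of the contour points.
4. **Attachment point.**  The polygon vertex closest to the axis wins;
   vertices tied within tolerance + 1 px are resolved toward the base.
   The wide tie window matters: simplified vertices along a lamina's
   inner edge deviate from the axis-offset curve by up to the tolerance,
   and with a bowed mid-rib a mid-edge vertex can otherwise shadow the
   true basal corner, which turns a 60-degree vein angle into a
   near-180-degree artifact.
5. **Vein angle.**  The interior angle between the two polygon edges
   incident to the attachment vertex, in (0, 180].  Edges shorter than
   twice the tolerance are skipped when selecting the incident edges:
   rounded lamina corners leave short chamfer edges that are not vein
   edges.
6. **Assembly.**  Laminas are assigned left/right by centroid against the
   axis (extended linearly to the borders), ordered by arc position, and
   summarized into the two angle lists, their means and standard
   deviations, and the counts `LM_N = LM_N_LT + LM_N_RT`.

As a consistency check (not a production path), the mid-rib can be
re-derived from the laminas alone: the closed left and right
lamina-plus-vein objects leave a band between their inner edges; the
per-row bounds are median-filtered (a vein stroke crossing perturbs only a
few rows), interpolated as half-widths about the axis, and shrunk by a
2 px clearance.  Over the lamina-flanked span this reconstruction overlaps
the true mid-rib with IoU well above 0.6; the petiole cannot be
reconstructed this way, being lamina-free by definition.

## The trait vector

Each normalized leaf yields 266 named traits in a fixed registry order
(`trait_registry()`):

* **GEO (30):** blade length/width/area/perimeter, convex hull area,
  solidity, aspect ratio, the scaling factor, the five component areas,
  the eight area-ratio indicators (`X_A_Ratio = 100 |X| / |BD|` for
  MR, VS, VV, LM, MZ plus `MR_VS`, `MR_VV`, `VS_VV`), the three
  excess-area overlap indicators
  `EVA_X_Y_2_Z = 100 (|X| + |Y| - |Z|) / |Z|` (zero exactly when X and Y
  partition Z), left/right lamina and blade areas, and the lamina and
  venation hull areas.  Convex hull areas use the shoelace formula
  corrected to pixel counts via Pick's theorem, so a solid convex region
  has solidity exactly 1.
* **VEN (20):** petiole, mid-rib and apex lengths, petiole pixel area,
  lamina counts (total/left/right), the two basal lamina areas, vein
  angle means and standard deviations per side, venation and vein
  skeleton lengths, skeleton endpoint and branch-point counts, vein
  density (VV skeleton length per blade area), and the petiole fraction
  `PE_L / MR_L`.
* **CLR (216):** for each of the 6 components x 6 color spaces x 3
  channels, the mean and the population standard deviation (divisor N) of
  the masked pixels.  Conventions: HSV hue in [0, 360), S and V in
  [0, 1]; `LAB` is 8-bit-quantized CIE L\*a\*b\* (L·255/100, a+128,
  b+128, clipped), `CIELab` the floating-point version (L in 0-100);
  `LUV` is CIE L\*u\*v\*; `YCrCb` follows ITU-R BT.601; sRGB primaries
  and D65 white throughout.  The two L\*a\*b\* entries deliberately
  differ only in quantization — field pipelines commonly list both under
  these two names without further distinction, and keeping both
  preserves the 6 x 6 x 3 x 2 = 216 layout.

Geometry and venation trait names that appear in the field's manual
measurement tables (`BD_L`, `PE_L`, `LM_Ave_ANG`, ...) are used verbatim;
the registry completes the sets to 30 and 20 with standard morphometrics,
and isolates the composition in one file so entries can be swapped without
touching extraction code.  Pixel lengths convert to millimetres with the
camera constant 4.785e-2 mm/px (`pixels_to_mm()`; 40 px = 1.914 mm).

## Cohort statistics

* **Agreement with manual measurement:** `R2 = 1 - SS_res / SS_tot` of
  computed against manual values, MAE, and MAPE.
* **Positive-back differences:** `PB_X = 100 (X_pos - X_back) / X_pos`,
  signed relative to the positive face so adaxial deficits are negative.
  The reference could equally be the back face or the pair mean; the
  convention is isolated in one function and recorded in its output.
* **Color feature importance:** a single CART classification tree (Gini
  impurity).  Importance sums the impurity improvements of each feature's
  primary splits only — surrogate and competitor splits are excluded, so
  an uninformative feature cannot borrow credit from a correlated one —
  scaled to percent.
* **PCA:** columns are z-score standardized first (geometry, venation and
  color traits live on incommensurable scales; unstandardized PCA would
  be dominated by pixel areas), constant columns dropped with a warning;
  the top 10 components and their explained-variance fractions are kept
  per feature set (GEO/VEN/CLR/COM), and the 40 PC score vectors feed a
  correlation matrix.
* **Clustering:** agglomerative on Euclidean distances between PC scores.
  Ward linkage is the default (compact, similar-size groups are the
  useful output for cultivar grading); single/complete/average are
  available.

## The synthetic-leaf generator

Real leaves come with no ground truth, so every stage is validated on
generated leaves (`generate_leaf()`): an ovate blade (a smooth
beta-profile outline about the mid-rib), a bowed mid-rib whose petiole
segment is about three times the vein stroke width, straight second-order
veins attached at known arc positions and angles, laminas as the regions
between consecutive veins after eroding a marginal band, and a flat-color
painting with seeded Gaussian noise.  The generator emits exact ground
truth: component areas (pixel counts of the emitted masks), mid-rib arc
length, petiole length, per-lamina side, order, attachment and angle.

Default dimensions place the blade at 500-850 px length and 380-620 px
width with 3-6 veins per side — the size and complexity range of detached
lettuce leaves photographed at about 20 px/mm.  Two generator choices
deserve explanation:

* **Angle sequences are a bounded random walk** (free opening toward the
  apex, steepening capped at +10 degrees between consecutive veins):
  two straight veins whose angles increase sharply would cross inside the
  blade, a layout real venation does not produce and the renderer cannot
  express.  Within a sequence, angles span 40-120 degrees.
* **The true petiole length is the rendered one.**  The marginal band and
  the vein-stroke clearance displace the first lamina slightly apex-ward
  of the nominal first attachment; since the petiole is by definition the
  stalk up to the first lamina, ground truth records the exact contact
  arc of the rendered basal laminas (the nominal attachment is kept as
  `PE_L_nominal`).

On 20 such leaves the pipeline recovers lamina counts exactly, petiole
length within 5 px, and vein angles with a mean absolute error under 5
degrees — tighter than the ~8 degree agreement reported between automated
and manual angle measurement on real leaves.  What the generator does
*not* emulate — segmentation errors, leaf folds, twisted or crossing
veins, multiple main veins, specular highlights — bounds what these tests
show: they validate the measurement geometry, not robustness to imperfect
masks.  Leaves violating the component model (no laminas found, ambiguous
mid-rib) are flagged invalid by the pipeline rather than silently
dropped.

## Numerical choices and degenerate inputs

* Foreground threshold 127 on 8-bit masks; 8-connectivity for foreground
  components, 4-connectivity for regions cut by skeletons (the dual, so
  regions cannot leak through diagonal skeleton steps); skeleton tips are
  extended to the blade border before region partitioning.
* Empty denominators (e.g. `MR_VS_A_Ratio` with no veins) yield `NA`,
  serialized as empty CSV cells — never 0.
* An empty component's 36 color traits are `NA`; a single-class label
  vector is an error for the decision tree; `k` outside 1..n is an error
  for clustering.
* A mid-rib whose two box halves tie exactly triggers the lower-half
  tie-break with a warning; a mid-rib skeleton with more than two
  endpoints after spur pruning selects the longest end-to-end path with a
  warning.
* End-to-end runs are deterministic given the configuration and seeds;
  per-leaf failures are logged, flagged and skipped, and the exit status
  of the command-line `run` reflects the failure count.

## Problem sizes used in the shipped checks

The test suite exercises reduced leaves (360 x 260 px blades) for unit
checks and full-size leaves (the generator defaults) where a bound is
scale-sensitive: the 20-leaf rotation sweep, the 20-leaf parameter
recovery, and the 40-leaf two-regime clustering separation.  The regime
comparison is a controlled experiment: the two groups differ only in
their vein-angle distribution (blade geometry held at the generator
defaults), so the venation principal components reflect the manipulated
factor rather than incidental size variation.  The
acceptance script reruns the width contract and the rotation sweep at
full scale from scratch.

## Known limitations

* The blade model is a single ovate outline; lobed or serrated margins,
  folds and overlapping tissue are not generated and not claimed.
* Straight second-order veins only; strongly curved veins would shift
  attachment corners and bias angles by a few degrees.
* The flip criterion relies on recorded acquisition orientation; no
  image-based handedness detection is attempted.
* Cohort statistics reported for real cultivar collections (means of
  area ratios, manual-agreement coefficients, importance rankings) are
  data-dependent; this package reproduces the machinery, not those
  numbers.
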