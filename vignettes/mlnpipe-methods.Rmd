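---
title: "Fusion, anatomical filtering and short-axis measurement of mediastinal lymph nodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusion, anatomical filtering and short-axis measurement of mediastinal lymph nodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlnpipe)
```

## Scope and model

`mlnpipe` implements the computational stages of a mediastinal lymph-node
analysis pipeline that sit downstream of any voxel segmentation model:
fusing an ensemble's binary predictions into pseudolabels, removing false
positives with anatomical constraints, measuring each surviving node's
short axis length (SAL) on axial slices, and scoring detection,
segmentation and observer agreement. Training segmentation networks and
computing organ segmentations are out of scope; the package consumes and
produces label volumes in NIfTI format and is agnostic to where they came
from.

Volumes are 3D integer arrays with strictly positive per-axis spacing in
mm. Internally the package uses R's native column-major `(x, y, z)` array
order with 1-based indices and the third axis as the axial (slice)
direction by default; the physical position of voxel `(i, j, k)` is
`origin + (c(i, j, k) - 1) * spacing`. Stating one convention across all
modules is deliberate: mixed index conventions are the classic source of
axis bugs in volumetric code.

## Pseudolabel fusion

Ensemble members vote voxel-wise, and the default fusion is the **union**:
a voxel is foreground if at least one member predicted it. The union is
recall-first — a node missed by the fused pseudolabel can never be
recovered by downstream training, while a false positive can still be
filtered — so the pipeline deliberately trades precision here and wins it
back at the anatomical filter. Majority-vote and k-of-n fusion are
provided only for ablation. Fusion requires binary masks on one grid;
soft probability maps are not supported, because the pipeline's contract
is label-in/label-out.

Postprocessing, shared between pseudolabel generation and inference,
fills enclosed cavities, extracts 3D connected components and removes
components of at most 30 voxels (roughly 3 mm at typical chest CT
resolution — below a measurable node). The threshold is inclusive: a
30-voxel component is removed, a 31-voxel one kept. Hole filling runs
before the size rule, and is 3D by default since components are 3D
objects; per-slice 2D filling is available as an option. Component
connectivity defaults to 26 (faces, edges and corners), the most
permissive choice, which avoids splitting thin nodes; 6 and 18 are
exposed as parameters. Component ids are assigned in order of first
encounter during a column-major scan, so labelling is deterministic
across runs and platforms.

## Anatomical filtering

False positives are removed in two ordered stages.

**Extramediastinal filtering** uses the lungs as the spatial anchor. On
every axial slice where both lungs appear, the region of interest (ROI)
is the tight 2D bounding box around both lung cross-sections minus all
lung voxels — the inter-lung compartment where mediastinal nodes reside
by definition. Slices lacking either lung contribute no ROI, so
candidates above or below the lungs are excluded along with intrapulmonary
and lateral ones. A candidate is kept when its centroid voxel lies inside
the ROI. Centroid membership was chosen over any-voxel or majority-voxel
membership because nodes legitimately abut the ROI border and a single
protruding voxel should not change their fate; the alternatives are
exposed as a parameter.

**Intramediastinal filtering** removes candidates that significantly
overlap one of 17 mediastinal structures (trachea, bronchi, lungs, left
and right subclavian arteries, superior vena cava, pulmonary veins, left
and right common carotid arteries, left and right brachiocephalic veins,
brachiocephalic trunk, left atrial appendage, aorta, heart, esophagus,
pulmonary artery) — such candidates are typically misclassified vessels.
The overlap fraction is computed **per structure** and the maximum
decides; fractions are never summed across structures, because nodes
naturally touch several vessels at once with small individual overlaps.
The removal threshold is 40 % and inclusive ("at least 40 % of voxels
labeled in both"), set high on purpose: enlarged nodes have genuinely
ambiguous boundaries against their anatomical neighbours and a low
threshold would discard correct detections. The lungs appear in the
structure list as well, redundantly with the ROI stage; the redundancy is
kept because the two rules fire on different geometry (centroid vs 40 %
overlap). Atlas masks are consumed as files (one binary mask per
structure, or a JSON/YAML manifest); the package never invokes a
segmentation tool.

The stage order is observable: a component inside a lung is tagged
`extramediastinal` even if it also overlaps a vessel, matching a
first-ROI-then-overlap reading of the pipeline. Filtering is a pure
selection — components are never split, merged or modified — and every
input component receives exactly one decision, so `|kept| + |removed| =
|input|` by construction.

## Short-axis length

SAL is defined on 2D axial cross-sections. For a 2D-connected component
C with contour ∂C, the long axis is the point pair maximising the
pairwise Euclidean distance over ∂C × ∂C; u_LA is its unit direction;
and SAL_2D(C) is the longest chord between contour points perpendicular
to u_LA. Contour points are centers of voxels with at least one
4-neighbour outside the set, scaled to mm by the in-plane spacing.

Two numerical choices make the definition computable on a discrete grid:

- **Perpendicularity tolerance.** Exact perpendicularity is measure-zero
  on lattice contours, so chords within 3° of perpendicular qualify. If
  no pair qualifies, the tolerance doubles (3°, 6°, 12°, 24°, capped at
  45°) until one does; if none exists at 45° the cross-section is flagged
  degenerate with SAL 0. The doubling schedule guarantees termination
  with bounded angular error, and the comparison is done on squared
  quantities (`dot² ≤ d²·sin²θ`) to avoid square-root asymmetries.
- **Tie-breaking.** Among equally long candidate pairs the
  lexicographically smallest endpoint pair wins (each pair first ordered
  internally), making results deterministic and exactly reproducible by a
  brute-force evaluation of the defining argmax equations. The long-axis
  search is restricted to convex-hull vertices — diameter endpoints are
  always hull vertices — and the test suite verifies exact agreement with
  an all-pairs oracle on hundreds of random lattice contours.

A 3D node is measured by computing the long/short axes on every axial
cross-section (per 2D-connected subset when a slice intersects the node
in several pieces, since the equations are defined on a connected C) and
taking the **maximum** per-slice SAL as the node's SAL, with the argmax
slice as the reference slice and ties going to the lowest slice index.
The maximum-SAL rule reflects the clinical practice of measuring a node
at its widest short axis; it is exposed as the slice-selection strategy
since other conventions (e.g. largest-area slice) exist. All distances
are in-plane — no oblique 3D calipers — matching the per-axial-slice
caliper protocol. Nodes are classified *enlarged* iff SAL ≥ 10 mm.

Measurement deltas between two observers of the same node are ΔSAL
(absolute SAL difference, mm), ΔSlice (absolute reference-slice
difference) and ΔAngle (angle between short-axis directions folded to
[0°, 90°], because an axis is undirected).

## Evaluation

Detection uses any-voxel overlap as the hit criterion with greedy
one-to-one resolution by descending overlap (ties by id pair) — the most
common convention in the lesion-detection literature; an IoU floor is
available as a parameter. Precision and recall follow from the matched
pairs, with an `NA` marker for empty denominators. Segmentation quality
uses the Dice coefficient (both-empty masks score 1.0 by convention,
with a message) and the average symmetric surface distance in mm, with
surfaces defined by the 6-neighbourhood and the two directed means
averaged; ASSD is an error on empty masks. Classification agreement is a
2×2 normal/enlarged confusion matrix with per-bin means and standard
deviations of each rater's SAL and of the deltas; percent agreement is
the diagonal share rounded to the nearest integer, while filtering
reductions are reported at one decimal — matching the conventional
printed precision of each quantity.

## Snapshot-ensemble schedule

The cyclical schedule is provided as pure functions so any trainer can
consume it. Within each cycle of 1000 epochs the rate starts at 0.1,
decays until epoch 900 and stays at 0.01 for the final 100 epochs; per
cycle the last four checkpoints of the plateau are retained, so the
default yields 24 members. The published anchors fix only the endpoints
of the decay; the shape in between is polynomial with exponent 0.9, the
convention of the 3D segmentation frameworks this schedule is normally
paired with, with linear decay available via a configuration switch.
Checkpoint granularity is per-epoch within the plateau, which makes
"last four checkpoints" well defined. Epochs are 0-based and global;
all retained epochs provably map to the floor rate.

## Synthetic phantoms

The phantom generator emulates the *statistical structure* the pipeline
assumes: two ellipsoidal lungs flanking a mediastinal gap, full-height
cylindrical "vessels" drawn from the 17-structure vocabulary, and
axis-aligned ellipsoidal nodes. Axis alignment is deliberate — the
equatorial cross-section of an axis-aligned ellipsoid with in-plane
semi-axes a ≥ b is an ellipse with exact analytic SAL 2b, so ground truth
requires no slicing algebra that would itself need testing. Rotated
ellipsoids are a known limitation. The default grid is 128 × 128 × 96 at
(0.7, 0.7, 1) mm: small enough for seconds-scale tests, with the axial
anisotropy of real CT deliberately retained to catch spacing bugs.

Planted node kinds map one-to-one onto pipeline decision paths: `true`
nodes must survive; `lung_fp` nodes must be removed as extramediastinal;
`vessel_fp` nodes are positioned by a line search so their realised
overlap with a target structure is within 0.02 of a requested fraction
and must be removed by the overlap rule; `speck` blobs (random connected
growths of a chosen voxel count) must be removed by the size rule.
Ensemble diversity is emulated by per-member node dropping, ±1-voxel
morphological jitter and spurious specks, all driven by one named seed;
phantom volumes, truth tables and perturbations are bit-identical under a
fixed seed.

What phantom tests do **not** show: real CT intensity structure, soft
node boundaries, deformable anatomy, segmentation-model behaviour, or
nodal-station geometry. Passing them demonstrates that the
post-segmentation computations are correct, not that any particular
segmentation model performs well.

## Problem sizes and verification

The test suite verifies the caliper routines against an all-pairs
brute-force oracle on 500 random lattice contours of up to 200 points
(exact equality, including tie-breaks), SAL parameter recovery on 100
random ellipsoids with semi-axes 2–15 mm at (0.7, 0.7, 1) mm spacing
(≥ 95 % of nodes within one in-plane pixel diagonal, ≈ 0.99 mm, of the
analytic 2b — the residual misses are small or axially thin nodes where
voxelisation error is inherently close to the bound), and the canonical
five-node phantom end to end. Published worked examples — filtering
reduction percentages, classification-agreement percentages, cohort node
accounting and the 24-checkpoint schedule — are recomputed from their
input counts by `scripts/acceptance.R`.

## Known limitations

- SAL is systematically underestimated by up to about half a voxel per
  endpoint, because contours are voxel centers; sub-voxel contour
  interpolation is a non-goal.
- The ROI construction (per-slice bounding box of both lungs minus lung
  voxels) is one concrete reading of "the region between the lungs";
  other constructions (convex hull, fixed margins) would admit slightly
  different border cases.
- The greedy detection matcher is order-dependent only through its
  deterministic tie-break; a Hungarian assignment could differ on
  contrived overlap ties.
- Atlas quality is taken on trust: the filter is only as good as the
  organ masks supplied to it.
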