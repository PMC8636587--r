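---
title: "Automatic measurement of lower-limb torsion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic measurement of lower-limb torsion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Femoral and tibial torsion — the axial-plane rotation of a bone's distal
reference axis against its proximal reference axis — are measured
clinically on axial MRI stacks of the hips, knees, and ankles.
Radiologists draw reference lines on chosen slices and read off projected
angles; the choice of slice, line, and method introduces inter-reader
variability of several degrees. `limbtorsion` implements a fully
automatic pipeline in two stages that mirror clinical reading:

1. **Segmentation.** A 3D U-net labels every voxel as background, femur,
   tibia, or fibula.
2. **Deterministic geometry.** Anatomic landmarks are extracted from the
   label masks, four axial reference lines are constructed, and the two
   torsion angles are the signed projected angles between the proximal
   and distal line of each bone.

All geometry operates in a canonical LPI voxel frame (x right-to-left,
y anterior-to-posterior, z superior-to-inferior); NIfTI inputs are
reoriented on read. The mm coordinate of voxel `i` along an axis with
spacing `s` is `(i - 0.5) s`.

## Reference lines

* **Proximal femoral line (neck axis).** The femoral head centre is the
  argmax of the anisotropic Euclidean distance transform of the femur
  mask, restricted to the proximal half of the bone's z-extent — the
  centre of the largest inscribed sphere, whose radius also estimates the
  head radius. Scanning distally from the head slice, the first slice
  whose in-plane femur component (the one containing the head projection)
  reaches `1.6 x` the head diameter in maximum in-plane extent is the
  most proximal slice showing head, neck, and trochanter together; the
  neck axis is the major second-moment principal axis of that
  cross-section, oriented toward the head. If no slice qualifies, the
  widest slice is used and flagged. A rotationally degenerate
  cross-section (eigenvalue gap below 2 %) falls back to the x axis with
  a flag.
* **Posterior condylar lines (distal femoral, proximal tibial).** The
  condylar slice is the one maximizing the spacing-weighted convex-hull
  area of the bone cross-section (exact ties: distal for the femur,
  proximal for the tibia). The cross-section is split at its centroid
  perpendicular to its major principal axis; in each half the condylar
  point is the centroid of the posterior band (all voxels within
  `max(2, 2.5 x spacing_y)` mm of the half's posterior extreme — a
  sub-voxel, protrusion-robust estimate of the posterior pole), and the
  two points are connected, oriented medial-to-lateral. A cross-section
  whose major axis runs anteroposteriorly is rejected as degenerate.
* **Distal tibial line.** On the most distal slice where both tibial and
  fibular cross-sections reach 25 mm², the two cross-section centroids
  are connected, oriented tibia-to-fibula.

The slice-selection thresholds (1.6x head diameter, 25 mm²) are this
package's own calibrated defaults, exposed as function arguments: the
landmark concepts are standard, the constants are not. Two further choices are deliberate deviations from the
plainest reading of those concepts, both for robustness under in-plane
rotation of the anatomy: the medial/lateral split uses the cross-section
principal axis rather than a fixed vertical line (equivalent for an
unrotated knee, stable when the anatomy is oblique), and the condylar
point is a posterior-band centroid rather than a single extreme voxel
(a one-voxel extreme jumps by half a chord width under rotation and
onto voxel-scale segmentation bumps — several degrees of line direction
at clinical voxel sizes). Only the largest
connected component per bone class is used; smaller fragments are
treated as segmentation noise.

## Sign convention

`projected_axial_angle(u, v)` is the signed angle from `v` to `u`
reduced to (-90, 90] degrees; reference lines are undirected, and
clinical torsion magnitudes stay far from the wrap. Femoral torsion is
positive for antetorsion (neck axis anterior to the condylar line);
tibial torsion is positive for external torsion (distal tibio-fibular
line externally rotated against the tibial condylar line). For left
limbs the x axis is mirrored before the angle is taken, so both sides
report on one scale. No inter-stack registration is applied: each
stack's canonical axes are trusted, matching the acquisition protocol's
neutral positioning.

## The segmentation network

The U-net has depth 6 with 16 filters at the top level, doubling at each
pooling step to 512. Each level applies two 3x3x3 convolutions with
instance normalization (batch size is 1) and ReLU; the final 1x1x1
convolution and softmax give per-voxel class probabilities. Up-sampling
is trilinear interpolation followed by a 1x1x1 convolution. Three
choices merit notes:

* **Anisotropic pooling.** An axial stack of ~29 slices cannot be pooled
  six times along z; a level pools z only while the current z-extent is
  at least 8 (and even), otherwise in-plane only. In-plane extents must
  be divisible by 2^(depth-1) = 32, which `crop_or_pad()` guarantees.
* **Trilinear up-sampling** is used throughout: the data are 3D, and the
  occasionally-seen "bilinear" naming only fits the in-plane analogue.
* **One network for all three regions** with four output classes: the
  shared network lets region context (head + neck vs. paired tibia +
  fibula) disambiguate femur from tibia, and nothing in the task demands
  per-region models.

The training loss is the sum of soft Dice losses over the foreground
classes *present in the target* plus voxel-averaged categorical
cross-entropy over all classes (`eps = 1e-5` in the Dice denominator).
Restricting Dice to present classes makes the loss equal its
cross-entropy value on background-only patches instead of paying a
constant penalty per absent bone. Optimization is Adam at batch size 1
with initial learning rate 0.001. The schedule halves the rate whenever
the 50-iteration moving average of the training loss fails to improve by
a relative 1e-3 for 100 consecutive iterations (minimum 1e-6): only the
halving factor is fundamental; window, tolerance, patience, and floor
are this package's defaults. Augmentation applies, with probability 0.5,
one family drawn uniformly from motion, ghosting, spiking, and bias
field; the amplitude ranges (rotation <= 5 deg, ghost intensity 0.3,
<= 3 spikes, order-3 bias field of roughly +/- 30 %) are likewise
package defaults. All forward/backward kernels
are double-precision (im2col + BLAS) and every training run is bitwise
reproducible from its seed. Deep supervision and residual connections
are assumed absent; validation-loss-driven scheduling is not used —
the moving *training* loss is monitored, as described.

## The phantom generator

Clinical torsional-MRI data are rarely shareable, so training and validation use a
parametric bone phantom whose torsion is known analytically. A limb is
assembled from spheres and cylinders: femoral head ball, horizontal neck
cylinder rotated by the femoral torsion angle anterior to the condylar
tangent, greater trochanter, vertical shaft, and two equal-radius
posterior condylar lobes whose common posterior tangent defines the
distal femoral line; the tibia mirrors this, and at the ankle a thin
fibular cylinder realizes the tibial torsion against the proximal
tibial tangent. Equal-radius lobes make the posterior tangent — and so
every reference line — exactly recoverable: the posterior pole of each
lobe sits directly posterior to its centre, so the pole-to-pole line is
parallel to the centre-to-centre line at any rotation, and voxelization
is the only error source (measured below 0.35 degrees at 1.2 mm in-plane
spacing).

Default grids emulate the acquisition: 29 axial slices per joint at
0.6 x 0.6 x 6.5 mm, a field of view wide enough for a bilateral pelvis,
bright bone (1.0) on dark background (0.0). Geometry defaults (head
radius 10.5 mm, neck 25 mm, condylar radii 13/12 mm, half-separations
16/14 mm, fibular offset 22 mm) approximate adolescent anatomy — the
typical torsional-MRI referral population — and a global `scale` fits
phantoms into small training patches. Optional Gaussian intensity noise and one artifact
family per stack complete the intensity model.

What the phantom does *not* emulate: textured bone marrow, cartilage and
epiphyseal plates (a documented failure mode of the real system),
cortical/trabecular contrast, partial-volume gradients at 6.5 mm slices,
orthopedic hardware, and anatomical shape variation beyond the
parametric family. Passing the phantom suite therefore demonstrates that
the geometry pipeline is correct and stable and that the network can
learn this segmentation task end-to-end — not that the trained weights
transfer to clinical MRI.

Segmentation-like corruption for robustness experiments treats each
bone's binary image as an intensity channel: noise and one random
artifact per stack, a 3x3 in-plane box smoothing (real segmentation
errors are spatially coherent), a 0.5 threshold, hole filling, and
largest-component selection. This perturbs landmarks the way imperfect
segmentations would.

## Evaluation statistics

`dice_coefficient` (both-empty defined as 1, flagged), `pearson_r`
(t-transform p, zero-variance flagged), `mean_abs_difference`
(t interval on |differences|), and `icc_single`. "Single scorings, not
adjusted" is read as the two-way random-effects, absolute-agreement,
single-rater ICC computed from the ANOVA mean squares, with the standard
F-based confidence bounds; the two-way consistency variant is exposed
behind `type = "consistency"` because reports of "single-score ICC"
do not always pin the model down. Degenerate tables (zero total
variance) return
`NA` with a flag rather than an error.

## Problem sizes and numerical choices

The validation suite and the acceptance script run, by design, at desk
scale:

* recovery and invariance grids use 128-voxel / 1.2 mm in-plane phantom
  stacks (half the acquisition resolution; voxelization error stays well
  inside the 1-degree tolerance);
* the training experiment uses the full depth-6/16-filter network on
  64 x 64 x 16 patches at 1.5 x 1.5 x 8 mm, 20 training phantoms (60
  stacks), 5 held-out phantoms, 220 iterations — enough for held-out
  foreground Dice near 0.9 on this task;
* oracle-equivalence checks run 100 seeded random instances per
  statistic.

Other numerical conventions: resampled shapes round half away from zero
with a one-voxel floor; label resampling is nearest-neighbour; argmax
ties in mask prediction resolve to the lower class code; constant
volumes normalize to zeros; the instance-norm epsilon is 1e-5; distance
transforms treat the grid boundary as background.

## Known limitations

* DICOM series ingestion is not provided; the supported on-disk format
  is NIfTI.
* The manual reference methods (Reikerås, Tomczak, Murphy, bimalleolar,
  talus) are out of scope; only the automatic method — closest to the
  Lee and ellipses methods — is implemented.
* No shape-model regularization of implausible segmentations, no
  inter-stack obliquity correction, and no claims about clinical
  transfer of phantom-trained weights.
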