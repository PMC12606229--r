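---
title: "Mapping connective-tissue architecture in 3D colour volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping connective-tissue architecture in 3D colour volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctfiber)
```

## The problem

Collagen-rich connective tissue — tendon, ligament, fascia, organ capsules —
forms a continuous, geometrically intricate network through the whole body.
Cryo-section photography yields RGB image stacks in which collagenous
structures occupy a distinctive, nearly white region of colour space, so the
network can be reconstructed in 3D from colour alone. Two local descriptors
then characterise its architecture at every voxel:

* **minimum thickness** — how thin the local sheet or cord is, measured as
  the shortest chord through the voxel over many directions; and
* **structural anisotropy** — whether the local tissue is *fibrous* (one
  dominant orientation, e.g. a tendon), *planar* (two strong in-plane
  orientations, e.g. a fascia sheet), or *spherical* (no preferred
  orientation), derived from an orientation tensor.

`ctfiber` implements this pipeline end to end: colour segmentation,
isometric binning, ray-cast thickness fields, orientation-tensor fields with
Westin measures, per-anatomical-region statistics, and depth-coded
projections, all stored as compressed NIFTI-1. A family of synthetic
phantoms with exactly known geometry backs every stage with oracle tests.

## Colour segmentation

Each voxel's `(r, g, b)` triple is mapped through a configurable 3×3 linear
transform and assigned to the tissue class whose reference colour lies
nearest in Euclidean distance, provided that distance is within the class
threshold; otherwise the voxel is background. Two classes are typical
because connective tissue around organs and connective tissue embedded in
subcutaneous fat differ slightly in hue.

The transform, references and thresholds are deliberately configuration,
not constants: the colour constants appropriate to any particular
photographic setup are acquisition-specific, and publishing behaviour
rather than one set of constants makes the classifier reusable. The default
model (identity transform, two whitish references, threshold 40) is the one
the phantom tests exercise.

Post-processing follows two rules. Connected components of the class-union
foreground smaller than a size threshold are removed as artefacts
(26-connectivity — the most permissive choice, which avoids fragmenting
thin fascia; cleaning on the class union lets a small fragment of one class
survive when attached to a large body of another). Missing cross-sections
are reconstructed by signed-distance interpolation: each neighbouring valid
slice becomes a signed Euclidean distance field (positive inside the
foreground), the fields are blended linearly by fractional position in the
gap and re-thresholded at zero. Distance-field blending preserves shape
topology across gaps, where per-voxel intensity interpolation would smear
boundaries.

## Isometric binning

Ray casting is direction-unbiased only on isometric voxels, so anisotropic
stacks are first converted by summative binning: each output voxel counts
the source voxels (or their values) falling inside it. For integer spacing
ratios this is an exact block sum, and the total count is conserved
exactly. For non-integer ratios each source voxel's value is distributed
over the output voxels it overlaps in proportion to overlap volume —
separable per axis since the grids are axis-aligned — and the real-valued
counts are rounded half-up with a largest-remainder correction so the
rounded grand total is preserved. Counts are stored 16-bit unsigned;
overflow raises rather than wrapping.

## Thickness by bidirectional ray casting

Directions are the distinct integer lattice vectors with components in
`[-n, n]`, reduced to primitive generators (collinear duplicates removed)
and, for thickness, to one representative per antipodal pair: `n = 1` gives
13 axes, `n = 2` gives 49. Rays step by the integer generator, landing
exactly on voxel centres — deterministic and directly checkable against
enumeration oracles, with no sub-voxel interpolation.

For each foreground voxel and axis, both ray arms run until they leave the
foreground, leave the grid, or reach the scan-range cap (default 64
voxels). The chord is `(r⁺ + r⁻ + 1)·‖g‖·s` (centre voxel counted once, `s`
the voxel size in mm), and thickness is the minimum chord over axes. An
isolated voxel therefore measures `s`, an axis-aligned slab of `t` voxels
measures `t·s`, and values saturate at `(2·cap + 1)·s` deep inside bulk
tissue. Background voxels store 0 rather than NA so fields save directly to
NIFTI; consumers mask by the segmentation.

Two properties of integer-lattice ray casting are worth knowing:

* **Diagonal undercount.** On curved surfaces the minimum lattice chord can
  undercut the geometric diameter: the centre of a radius-10 ball measures
  `11·√3 ≈ 19.05` voxels along the body diagonal, not 21 along the axis.
  This is a deterministic property of the estimator, not noise.
* **Gap skipping and boundary truncation.** Generators with a component of
  ±2 (the `n = 2` set) hop two voxels per step and can jump across a
  structure thinner than 3 voxels, returning a spuriously short diagonal
  chord; exact plate-thickness recovery therefore uses the `n = 1` axes.
  Likewise rays stop at the volume boundary, so chords through voxels in
  the outermost grid columns are truncated and can only shorten the
  minimum. The acceptance tests assert exact plate recovery away from the
  grid rim and treat rim values as a documented boundary effect.

## Orientation tensors and Westin measures

At each foreground voxel, every signed direction of an *unreduced* lattice
set (default `n = 2`, 98 directions — both arms of every axis, so the same
number of orientations enters at every voxel) contributes a scan-ray vector
`xᵢ = rᵢ·d̂ᵢ`, where `rᵢ` is 1 plus the capped run length (cap 16 voxels)
and `d̂ᵢ` the unit direction. The orientation tensor is the dyadic sum

$$A \;=\; \sum_i x_i \otimes x_i \;=\; \sum_i r_i^2\, \hat d_i \hat d_i^{\mathsf T},$$

a symmetric positive-semidefinite 3×3 matrix whose eigenvectors are the
principal material axes and whose eigenvalues measure their strength. The
`r²` weighting is not a free knob — it falls out of the dyadic of `r·d̂`.
Balanced lattice direction sets make `A` an exact multiple of the identity
in isotropic surroundings (octahedral symmetry), which the tests exploit:
an isolated voxel gives `A = (26/3)·I` for the 26-direction set, and an
infinite one-voxel fibre along z gives `diag(26/3, 26/3, 26/3 + 576)` in
closed form.

Sorted eigenvalues `λ₁ ≥ λ₂ ≥ λ₃ ≥ 0` with `S = λ₁+λ₂+λ₃` yield the
sum-normalised Westin measures

$$c_l = \frac{\lambda_1 - \lambda_2}{S}, \qquad
  c_p = \frac{2(\lambda_2 - \lambda_3)}{S}, \qquad
  c_s = \frac{3\lambda_3}{S},$$

a partition of unity (`c_l + c_p + c_s = 1` identically, each in `[0, 1]`)
that maps directly onto RGB. The λ₁-normalised Westin variant exists but
does not sum to one; the sum-normalised family was chosen for exactly that
colour-mapping property. A voxel is classified by the argmax of the triple
— fibrous, planar or spherical — provided the maximum reaches a threshold
θ (default 0, pure argmax; ties break fibrous > planar > spherical). θ is
exposed because region statistics whose class percentages do not sum to
100% imply some exclusion rule, and users may want to emulate one.

Tensor fields are computed per voxel and then block-averaged (default 2×,
mean of member foreground tensors; averaging dyadic sums preserves
positive semidefiniteness), halving the grid resolution to keep whole-body
tensor volumes manageable. Colour encodings mirror the archival naming
scheme: `e1`/`e2` absolute eigenvector components, `westin` the measure
triple, `rank` categorical red/green/blue for fibrous/planar/spherical.

### Numerical choices

* Eigen-decomposition uses the symmetric solver in base R; eigenvalues
  within `10⁻⁹·λ₁` below zero are clamped to 0.
* Eigenvector signs are fixed deterministically: `e1` and `e2` get their
  largest-magnitude component positive, and `e3 = e1 × e2` completes a
  right-handed frame. (Applying the sign rule to all three vectors can
  contradict right-handedness, so `e3` follows the frame, not the rule.)
* Zero-trace tensors (background) carry a flagged all-zero Westin sentinel
  and classify as unclassified, code 0.
* Half-up rounding is used wherever real values become stored bytes
  (`round()`'s round-half-to-even would be seed-free but surprises users).

## Region statistics

Anatomical label maps — typically drawn at much coarser resolution than the
analysis grid — are upsampled by nearest-neighbour lookup of voxel-centre
physical coordinates. Per region, the table reports connective-tissue
volume (`count·s³`, reported in dm³), thickness mean and *population*
standard deviation (the data are a complete enumeration of the region's
voxels, not a sample; switching to the sample SD is a one-line change), and
the percentage of fibrous/planar/spherical voxels, the remainder to 100%
being unclassified. Voxels with region label 0 are excluded everywhere.

## Volume I/O

All four volume kinds are stored as gzip-compressed NIFTI-1, reading
spacing from the header pixel dimensions. Integer scalar grids pick the
smallest integer datatype that holds their range and round-trip bit-exactly;
real scalar fields (thickness) are stored as 32-bit float; tensor volumes
use the 6-component lower-triangle layout `(a11, a21, a22, a31, a32, a33)`
with the symmetric-matrix intent code (1005) and 64-bit float storage so
matrices round-trip exactly; colour volumes use the 24-bit RGB datatype
(code 128). The symmetric-matrix intent code is the standard choice, noted
as an assumption since archival files elsewhere may differ. Label names
travel in a two-column tab-separated sidecar (`<stem>.labels.tsv`) because
NIFTI has no native label-name field. NIFTI-2 is rejected with a clear
message; orientation matrices are not interpreted (spacing is honoured,
rotations are not).

## Phantoms: what the tests do and do not show

`make_phantom()` builds masks and truth labels from slabs, cylinders, balls
and cuboids by a voxel-centre inclusion rule with no partial-volume
antialiasing, so foreground counts are integer-exact against enumeration
oracles. `colorize_phantom()` renders truth labels as an RGB stack with
per-channel Gaussian noise; `corrupt_mask()` flips voxels independently at
a given rate. All stochastic operations take an explicit seed and leave the
global RNG state untouched.

The phantoms emulate colour-separable tissue classes, thin plates, cords
and isotropic bulk — the geometric regimes the descriptors must
distinguish. They do not emulate lighting gradients, texture, curved
fibres, partial-volume colour mixing or registration error. Passing the
phantom suite therefore demonstrates that the estimators are implemented
correctly and recover known geometry under their stated conditions; it does
not certify segmentation constants for any particular photographic dataset.

The study conditions frozen into the acceptance suite are: 64³ voxel
phantom grids (cylinder radius 2, slab thickness 3, corruption rate 1%,
channel noise σ = 10, component-size threshold 5); thickness cap 64 and
tensor cap 16 voxels; 1000 random dyadic-sum tensors for the Westin
identities; 20 random 16³ masks against the brute-force thickness oracle;
and a 131³ cube for cap saturation — sizes chosen so each stage is
exercised at a scale where its exact oracles are computable.

## Design decisions and known limitations

* **Scan-ray reading of the dyadic sum.** The tensor's `xᵢ` are the
  run-length-weighted scan rays themselves. An alternative reading
  aggregates per-voxel best directions over a neighbourhood, as in
  fascicle-tracing work; it is not implemented here — the scan-ray form
  uses the same number of orientations at every voxel and is the one the
  phantom oracles pin down exactly.
* **Chord thickness, not sphere fitting.** The local-thickness-transform
  family (largest inscribed sphere) is a different definition with
  different bias; this package implements the directional-minimum
  definition only.
* **Lattice angular resolution.** The default 49-axis set brackets the
  minimum chord within roughly 13°; finer sets cost linearly in time and
  sharpen both the thickness minimum and the tensor's angular resolution,
  at the price of stronger gap-skipping on thin structures (see above).
* **Segmentation constants are not portable.** The colour model is a
  behaviour class with configurable constants; deposited segmentations of
  any given dataset cannot be regenerated bit-exactly without the original
  constants.
* **No registration.** Cross-section alignment and anatomical labelling
  are upstream, manual steps; this package consumes their outputs.
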