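# ctfiber

Characterisation of collagenous connective-tissue architecture in 3D colour
volumes: segmentation, thickness mapping, orientation-tensor analysis and
regional statistics for cryo-section image stacks, with synthetic phantoms
for end-to-end validation.

## What it computes

Connective tissue (tendon, ligament, fascia, capsules) is segmented from
RGB cryo-section stacks by a colour-space classifier, cleaned of artefacts,
and binned to isometric voxels. Two per-voxel descriptors are then derived
from ray casting over integer lattice direction sets:

**Minimum thickness.** For every foreground voxel, both arms of each axis
are traced up to a 64-voxel scan range; the thickness is the shortest
chord, `min_axes (r⁺ + r⁻ + 1)·‖g‖·s` mm. An isolated voxel measures one
voxel size, a plate of `t` voxels measures `t·s`.

**Orientation tensor.** Every sampled direction contributes a scan-ray
vector `xᵢ = rᵢ·d̂ᵢ` (run length capped at 16 voxels); the dyadic sum

```
A = Σᵢ xᵢ ⊗ xᵢ = Σᵢ rᵢ² d̂ᵢ d̂ᵢᵀ
```

is a symmetric 3×3 matrix whose eigenvalues `λ₁ ≥ λ₂ ≥ λ₃` yield the
sum-normalised Westin measures `c_l = (λ₁−λ₂)/S`, `c_p = 2(λ₂−λ₃)/S`,
`c_s = 3λ₃/S` (`S = λ₁+λ₂+λ₃`; the triple sums to 1). The argmax
classifies each voxel as fibrous, planar or spherical. Per-anatomical-region
tables report volume (dm³), thickness mean/SD (mm) and the structural
percentages; depth-coded X-ray projections and slice images support visual
inspection.

All volumes travel as compressed NIFTI-1: scalar grids in the smallest
integer datatype (or float32 for real fields), colour volumes as 24-bit RGB
(datatype 128), tensor volumes as 6 lower-triangle components
`(a11, a21, a22, a31, a32, a33)` with the symmetric-matrix intent
(code 1005), label maps with a two-column tab-separated name sidecar.

## Worked example

A phantom with a 3-voxel plate (caudal half) and a thin cord (cranial
half) is colourised, segmented back, and measured:

```r
library(ctfiber)

spec <- phantom_spec(c(48, 48, 48), spacing = c(1, 1, 1), primitives = list(
  list(kind = "slab", axis = 3, center = 12, thickness = 3, class = 1),
  list(kind = "cylinder", axis = 1, center = c(24, 36), radius = 1.5, class = 2)))
ph  <- make_phantom(spec)
rgb <- colorize_phantom(ph$truth,
                        rbind(`1` = c(225, 215, 200), `2` = c(235, 225, 180)),
                        color_noise_sd = 5, seed = 1)

labels <- clean_artifacts(segment_collagen(rgb, color_model()), 5)
mask   <- volume3d((labels$values > 0) * 1, spacing = labels$spacing)
th     <- thickness_field(mask, lattice_directions(1), cap = 64)
fld    <- tensor_field(mask, lattice_directions(2, FALSE), cap = 16, output_bin = 1)
rank   <- structure_rank(fld)

reg <- array(0L, c(48, 48, 48)); reg[, , 1:24] <- 1L; reg[, , 25:48] <- 2L
regions <- label_volume(reg, label_names = c(`1` = "caudal", `2` = "cranial"))
print(compute_region_table(mask, th, rank, regions), digits = 4)
#>    region label volume_dm3 thickness_mean_mm thickness_sd_mm pct_fibrous
#> 1  caudal     1   0.006912             2.899          0.3612       1.157
#> 2 cranial     2   0.000432             2.192          0.7239     100.000
#>   pct_planar pct_spherical n_voxels
#> 1      98.84             0     6912
#> 2       0.00             0      432
```

The plate region is 98.8% planar with mean thickness 2.9 mm (3 mm inside,
shorter truncated chords at the grid rim); the cord region is 100% fibrous.
At a voxel on the cord's axis the tensor spectrum and Westin triple confirm
a fibre:

```r
A <- orientation_tensor(mask, c(24, 24, 37), lattice_directions(1, FALSE), cap = 16)
round(eigensystem(A)$values, 2)
#> [1] 602.67  31.67  27.67
w <- westin_measures(eigensystem(A))
classify_structure(w)        # c_l = 0.863, c_p = 0.012, c_s = 0.125
#> [1] "fibrous"
```

A command-line front end (`inst/cli/ctfiber`) exposes the stages as
subcommands (`phantom`, `segment`, `isobin`, `thickness`, `tensor`,
`regions`, `project`, `slice`, `run`); `run_pipeline()` executes a YAML
pipeline configuration and writes a run manifest with parameters and input
checksums.

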