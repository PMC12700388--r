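# skeletrace

Dimension-aware skeletonization and tracing of cryo-electron tomogram
segmentations, in R.

Semantic segmentation of a cellular cryo-electron tomogram labels voxels as
membrane, filament or macromolecule, but a bag of voxels is not yet a
quantitative object: membranes have arbitrary, varying thickness, filament
networks are solid tubes, and each macromolecule is a blob of many voxels.
`skeletrace` post-processes binary segmentations into the structure-specific
representations that downstream analysis actually needs:

* **membranes** — a one-voxel-thick *center-surface*,
* **filaments** — *centerlines*, assembled into a spatially embedded graph,
  split into filament instances, and exported as discrete 3D curves with
  local and global geometry (curvature, torsion, sinuosity, persistence
  length),
* **macromolecules** — one *center point* per particle.

It also provides a topology-aware segmentation comparison metric that is
robust to segmentation thickness, where the standard voxel Dice is not.

The package is aimed at cryo-ET practitioners post-processing outputs of
segmentation tools (neural-network probability maps or binary masks, MRC2014
format) and at method developers who need a reference implementation with
exact synthetic ground truth.

## Method

All three representations come from one primitive. A binary segmentation is
converted to a smooth *saliency map* S: the Euclidean distance transform of
the mask (foreground voxels carry the distance to the nearest background
voxel), smoothed with an isotropic Gaussian (σ = 2 voxels by default). A
pre-computed float saliency map (e.g. a network probability map) can be used
directly instead.

At every voxel the Hessian of S,

    H = [ S_xx S_xy S_xz
          S_xy S_yy S_yz
          S_xz S_yz S_zz ],

is computed by repeated finite differences and diagonalized analytically
(Cardano solution of the characteristic cubic, with a Jacobi fallback for
near-degenerate spectra), giving eigenvalues |λ1| ≥ |λ2| ≥ |λ3| with
eigenvectors v1, v2, v3. Non-maximum suppression retains a voxel x in the
dimension-d skeleton 𝒮_d iff its saliency strictly exceeds the trilinearly
interpolated values at x ± δ·v_j for every j ≤ 3 − d:

* d = 0 (blobs): maximum along v1, v2 and v3 — isolated center points;
* d = 1 (filaments): maximum along v1 and v2 — centerlines;
* d = 2 (membranes): maximum along v1 — center-surfaces.

Filament skeletons become a spatially embedded graph (nodes = skeleton
points, edges = all pairs closer than ε), cycles are removed by a minimum
spanning forest, branch nodes are split by keeping the straightest
(largest-angle) pair of incident edges, and each resulting path is an
ordered curve with computed geometry. Blob skeletons are reduced to one
center per particle by flat-kernel mean shift. For segmentation comparison,
the skeleton-based Dice at dimension d is the harmonic mean of

    TP_d = |𝒮_d(in) ∩ ref| / |𝒮_d(in)|     (topological precision)
    TS_d = |𝒮_d(ref) ∩ in| / |𝒮_d(ref)|    (topological sensitivity),

i.e. the fractions of each segmentation's skeleton contained in the *other
full segmentation* — insensitive to how thick either segmentation is.

Details, parameter guidance and numerical edge cases are in the methods
vignette, `vignettes/skeleton-tracing.Rmd`.

## Worked example

Detect particle centers in a synthetic blob segmentation and check the
membrane tracer, end to end:

```r
library(skeletrace)

# synthesize a tomogram-like segmentation: 20 ribosome-sized blobs
phantom <- blob_phantom(shape = c(128, 128, 128), n_blobs = 20, radius = 5,
                        min_separation = 20, seed = 1)
phantom$seg
#> <binary_volume> 128 x 128 x 128 voxels, voxel size 1 nm
#>   foreground voxels: 10477

# skeletonize at dimension 0 (blob centers), cluster to one center/particle
skel <- skeletonize(phantom$seg, d = 0, sigma = 2, delta = 1/3)
skel
#> <skeleton_cloud> d = 0, 35 points, voxel size 1 nm
centers <- mean_shift(skel, bandwidth = 5)
centers
#> <blob_centers> 20 centers from 35 points

# compare against the planted ground truth (radius/2 matching rule)
detection_f1(centers, phantom$truth$gt_centers, particle_radius = 5)
#> <detection_report> TP = 20, FP = 0, FN = 0, F1 = 1.0000

# membrane shells: trace the center-surface and check it stays inside
membrane <- membrane_phantom(shape = c(128, 128, 128), n_shells = 2, seed = 1)
surf <- skeletonize(membrane$seg, d = 2)
skeleton_precision(surf, membrane$seg)
#> <precision_report> correct = 10704, failed = 199, precision = 0.9817

# topology-aware comparison: a thicker version of the same membrane
thicker <- dilate(membrane$seg, 2, connectivity = "ball")
voxel_dice(thicker, membrane$seg)
#> [1] 0.7328068
dice_d(thicker, membrane$seg, d = 2)
#> <dice_report> d = 2: TP = 0.8598, TS = 1.0000, DICE = 0.9246
```

The raw NMS skeleton has a few maxima per blob (35 points for 20 particles);
mean shift with the particle radius as bandwidth merges them, and every
planted center is recovered within half a radius (F1 = 1). For the
membranes, 98.2% of center-surface points fall inside the generating
segmentation; the residue sits in a thin band just outside tightly curved
thin shells (analyzed in the vignette). Thickening a segmentation by two
voxels drops the voxel Dice to 0.73 while the skeleton-based score stays at
0.92 — the thickness robustness the metric is designed for.

A command-line wrapper over the same functions is installed at
`inst/scripts/skeletrace`:

```sh
Rscript inst/scripts/skeletrace phantom --kind membrane --shape 128 --seed 0 --out seg.mrc
Rscript inst/scripts/skeletrace skeletonize --in seg.mrc --dim 2 --sigma 2 --out skel.csv
Rscript inst/scripts/skeletrace trace --in skel.csv --epsilon 15 --out-prefix fil
```

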