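---
title: "Skeletonization and tracing of tomogram segmentations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skeletonization and tracing of tomogram segmentations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skeletrace)
```

This vignette is the package's own account of what it computes, which
assumptions that rests on, and where the numerical design was genuinely
open. The README shows the surface; this document explains the interior.

## 1. The model

A segmentation of a cryo-electron tomogram assigns voxels to structure
classes. For quantitative work each class needs a different reduced
representation: membranes are 2-manifolds (a center-surface), filaments are
1-manifolds (centerlines with connectivity), macromolecules are 0-manifolds
(one point each). The package treats all three with one primitive: the
skeleton 𝒮_d of a scalar *saliency* field S is the set of voxels that are
strict local maxima of S along the top 3 − d eigenvector directions of its
Hessian.

The underlying assumption is that S is smooth and ridge-shaped across each
structure: maximal at the structure's center (mid-surface, centerline, or
center point) and decaying outward. Two sources of S satisfy this:

* a probability/regression map from a segmentation network, used directly;
* a binary mask, converted via the Euclidean distance transform (foreground
  voxels carry the distance to the nearest background voxel; the volume
  border counts as background) followed by Gaussian smoothing. The distance
  transform makes the mid-structure maximal regardless of segmentation
  thickness — the property all downstream thickness-robustness rests on —
  and the Gaussian makes the field differentiable so that Hessian
  eigenvectors are meaningful.

At each voxel the Hessian (repeated central differences) is diagonalized,
eigenpairs sorted by |λ1| ≥ |λ2| ≥ |λ3|. The dimension logic: at a blob
center all three curvatures are comparable and all three directions must be
maxima; on a centerline the two transverse directions (largest |λ|) are
maxima while the along-axis direction is flat; on a center-surface only the
normal direction (v1) is a maximum. Non-maximum suppression probes
S(x ± δ·v_j) by trilinear interpolation and keeps x iff S(x) is strictly
larger than both probes for every checked direction.

## 2. Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `sigma` | voxels | 2 | width of the smoothing Gaussian. Smaller: sharper localization, noisier Hessians. Larger: merges structures closer than ~2σ. 2 voxels suits membranes/filaments a few voxels thick at ~1 nm voxel size. |
| `delta` | voxels | 1/3 | NMS probe step. Sub-voxel probing is consistent with a one-voxel-thick skeleton: a probe of several voxels would let a voxel dominate positions far outside its own neighborhood and thicken the skeleton. The parameter is exposed because the field also uses multi-voxel probes; `delta = 3` reproduces that reading. |
| `threshold` | saliency units | 0 | minimum saliency for a voxel to be evaluated. 0 evaluates everything (exact-zero far-field voxels can never pass the strict test). A positive threshold (0.3 was used in the filament-tracing example this default set follows) suppresses faint detections in Gaussian tails. Applied before NMS. |
| `spacing` | voxels | 0 (off) | voxel-grid subsampling of the skeleton; reduces isolated false detections and graph cost (10 is a practical value for filaments). |
| `epsilon` | voxels | 15 (CLI) | graph edge radius; must exceed the typical gap along a traced centerline (subsampling spacing sets the scale) but stay below the distance between distinct filaments. |
| `min_length` | nm | 0 | curve length filter; tracing workflows typically discard stubs (85 nm for microtubule-scale data). |
| `bandwidth` | voxels | — | mean-shift kernel radius, matched to particle size. The field's usage is inconsistent about whether this is the particle radius or diameter; the package applies the number literally, with no hidden factor. |

## 3. Graph processing

The epsilon-ball graph uses a strict inequality (‖x_i − x_j‖ < ε), a grid
hash for expected O(n log n) construction, and merges exactly coincident
points (zero-length edges have no direction and would break angle
computations). Cycles are removed per component by Kruskal's minimum
spanning tree on Euclidean edge lengths; in a Euclidean embedding this is
essentially unique, and exact ties are broken deterministically by
(weight, smaller id, larger id).

Branch splitting walks nodes in ascending id. At a node of degree m > 2 the
pair of incident edges with the largest mutual angle — the straightest
continuation — is kept; each remaining edge is re-attached to a fresh
duplicate node at identical coordinates, so the edge count is conserved and
the component count grows by exactly m − 2. Ties in the maximal angle keep
the pair first in ascending edge-index order; the choice is arbitrary but
reproducible. After splitting, every component is a simple path and becomes
an ordered curve (starting at the lexicographically smallest endpoint, so
output does not depend on traversal order).

## 4. Curve geometry

Discrete estimators were chosen for having closed-form validation targets:

* **curvature**: Menger curvature, 4·Area/(abc) over consecutive point
  triples. For points sampled on a circle it equals the inverse circle
  radius *exactly*, so the circle test is exact up to endpoint replication.
* **torsion**: for consecutive differences e1, e2, e3,
  τ = ((e1 × e2) · e3) / (|e1 × e2| |e2 × e3|). The sign carries
  handedness. The normalization was fixed analytically: on a sampled helix
  the expression converges to the Frenet torsion with coefficient exactly 1
  (verified symbolically and numerically during development, not fitted).
* **persistence length**: log-linear fit through the origin of the
  tangent–tangent correlation over lags up to half the curve length, using
  *segment* (chord) tangents. Centered-difference tangents average
  neighboring segments and inflate the estimate substantially. Per-curve
  estimates on chains only a few persistence lengths long are heavy-tailed;
  `pooled_persistence_length()` averages per-lag correlations across a
  filament population before fitting and is the estimator the package's own
  recovery tests rely on.

A "signed curvature" is deliberately not exported: no sign convention for
general 3D curves is well defined without a reference framing, so only the
unsigned κ and the signed torsion are reported.

## 5. Mean shift

Flat (uniform-ball) kernel: a seed at every input point, iterating
x ← mean(points within the bandwidth of x) until the displacement falls
below 1e-3 voxels or 300 iterations. Converged modes are merged when closer
than bandwidth/2: modes are ranked by how many input points fall within one
bandwidth (ties: lower seed index) and a mode is absorbed by any
better-ranked accepted center within bandwidth/2. Everything is
deterministic — no random seeding, no library-dependent defaults — and the
merge rule guarantees accepted centers are at least bandwidth/2 apart while
every input point is assigned to exactly one center.

## 6. Segmentation metrics

`dice_d()` skeletonizes both segmentations with identical parameters and no
subsampling, then takes the harmonic mean of the two skeleton-inside-the-
other-segmentation fractions. Point-in-segmentation tests use
nearest-voxel lookup (round half up), since segmentations are binary;
trilinear membership would be a modeling statement the mask cannot support.

`skeleton_precision()` reports correct/(correct + failed). The published
table this mirrors prints its formula upside down (failed/correct) while
its printed values follow correct/(correct + failed); the package follows
the values, which the test suite reproduces exactly from the printed
counts.

`detection_f1()` matches greedily in ascending pair distance under the
strict half-radius rule, each side matched at most once. Greedy matching is
not globally optimal in pathological overlap configurations, but with
particles separated by more than their radius the two coincide; the
assignment algorithm behind the published numbers is unstated, so the
simplest deterministic rule was chosen.

## 7. Phantoms: what they emulate, and what they do not

The generators produce binary masks with *exact* ground truth and a
mandatory seed:

* `membrane_phantom()` — unions of spherical shells, |‖x − c‖ − R| ≤ t/2,
  radii 18–32 voxels, per-shell thickness drawn from 4–7 voxels (real
  membrane segmentations have non-uniform thickness); ground truth samples
  the exact mid-spheres.
* `filament_phantom()` — tubes of radius 4 voxels around straight, helical,
  wormlike (discrete tangent random walk with prescribed persistence
  length) or branched (random trees, branch angles 60–150°) centerlines,
  rasterized as unions of balls along densely sampled polylines; ground
  truth is the centerline and its topology graph.
* `blob_phantom()` — packed non-overlapping solid spheres with minimum
  center separation; ground truth is the exact centers.

They emulate geometry and topology only. Real tomograms add the missing
wedge, contrast transfer, shot noise, segmentation errors, and structures
that touch; none of that is modeled (an additive-noise knob would not make
the phantoms realistic and is not pretended to). Consequently, passing the
phantom suites demonstrates correctness of the geometric pipeline — not
end-to-end performance on experimental data.

Two phantom-specific effects matter when reading test numbers:

* **Voxelized centerlines zig-zag.** A traced straight tube has geodesic
  length up to ~30% above its end-to-end distance, so sinuosity of traced
  (as opposed to analytic) curves is biased upward; recovery tests assert
  Hausdorff distance to the true centerline instead.
* **Tube phantoms are capsules.** The medial axis genuinely continues into
  the hemispherical end caps, so traced curves extend up to one tube radius
  beyond the ground-truth segment; tests compare against cap-extended
  centerlines and filter end-cap stubs with `min_length`.

## 8. The tangential ghost band: why curved thin shells cap the d = 2 precision

On a spherical shell the distance-transform profile is a tent in the radial
coordinate: piecewise linear, peaked at the mid-surface. After smoothing,
the radial second derivative is near zero along the tent's flanks, while
the tangential eigenvalues are −S′/r. On the outer flank both tangential
curvatures are negative, so v1 turns tangential there — and tangentially
the continuum field is *constant* on the sphere, so whether a voxel passes
the strict maximum test is decided by voxelization noise of order 1e-3.
A sparse band of such voxels just outside a thin shell's boundary (and
inside a thick one's) are genuine strict maxima of the discrete field:
re-deriving their eigenvectors with a dense eigensolver and probing the
definition literally confirms them. They are a property of the method on
tightly curved structures, not an implementation artifact, and they vanish
on flat membranes (where the tangential field is exactly constant) — which
is why large-organelle validation data supports higher precision than
small-sphere phantoms. For shells of thickness 4–7 voxels at σ = 2 this
band costs 1–2% of d = 2 skeleton points; the same mechanism makes the
skeleton-based Dice degrade gradually beyond about two dilations in the
thickness-robustness experiment, where it is nonetheless far more stable
than the voxel Dice and dominates it at every step when both inputs are
thickened equally. Practical mitigations on real data are the saliency
threshold and skeleton subsampling.

## 9. Numerical choices and degenerate inputs

* Strict inequalities throughout NMS: plateaus (constant regions) yield no
  skeleton, keeping it one voxel thick.
* Central differences by default; the literal one-sided (forward) stencil
  is available but shifts features by half a voxel, which would
  systematically displace skeletons of symmetric structures.
* The Cardano eigen-solution falls back to cyclic Jacobi when the relative
  eigenvalue gap drops below 1e-6 or the cross-product recovery of an
  eigenvector degenerates; eigenvector sign is meaningless downstream
  (both probe directions are used) and any orthonormal basis of a
  degenerate eigenspace is acceptable (the tests check reconstruction,
  not a particular basis).
* Trilinear probes clamp coordinates to the volume (replicate padding);
  the one-voxel border is excluded from NMS.
* Gaussian smoothing truncates the kernel at 4σ, renormalizes, and mirrors
  at volume faces, so no artificial ridges appear at the boundary.
* Empty inputs degrade gracefully with warnings: empty segmentations give
  zero saliency, empty skeletons give zero fractions in `dice_d()`, curves
  shorter than an estimator's support return zero-padded properties, and
  closed curves report infinite sinuosity.
* Iterated 6/26-connected dilation grows shapes by L1/L∞ balls and facets
  curved surfaces; `dilate(..., connectivity = "ball")` grows by exact
  Euclidean distance (via the distance transform of the padded complement)
  and is the right control when only thickness should change.

## 10. Problem sizes in the shipped tests

The suite validates on 128³ phantoms for the headline precision pools
(10 membrane + 10 filament phantoms, ~170k pooled d = 2 points), 96³ for
the dilation sweep, 32³ for the 20-volume brute-force NMS equivalence, and
exhaustive enumeration for graphs of ≤ 8 nodes; curve estimators are
validated on 100–200-point analytic circles, helices and 50 wormlike
chains of 200 segments. These sizes were chosen so the full suite and the
acceptance script each complete in minutes on one CPU while keeping every
pooled statistic stable to well under the tolerances asserted.

## 11. Known limitations

* Isotropic voxels are assumed everywhere (the distance transform and all
  geometry use a single voxel size).
* The d = 2 path extracts center-surface *points*; surface meshing or
  surface-instance topology is out of scope (connectivity of membrane
  instances falls out of the filament-style graph components if needed).
* Mean shift assumes roughly equal particle sizes per run — one bandwidth
  per invocation.
* MRC2014 I/O is deliberately minimal: little-endian files, modes 0/1/2/6,
  no extended-header dialects.
* On tightly curved thin structures the d = 2 skeleton carries the
  tangential ghost band of §8; a saliency threshold or subsampling is the
  practical mitigation.
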