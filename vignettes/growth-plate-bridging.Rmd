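---
title: "Quantifying growth-plate bridging and its mechanics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying growth-plate bridging and its mechanics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physis)
```

## Overview

`physis` turns a microCT volume of a long-bone extremity into (i) a census of
the bony bridges that cross the growth plate, (ii) a map of their areal
number density over the joint surface, and (iii) a linear-elastic estimate of
how they redistribute compressive load. This vignette records the method in
full, including every numerical choice, what the synthetic phantoms do and do
not establish, and the package's known limits.

## Image model and conventions

A `volume3d` is a 3D array of gray values with an isotropic voxel size in
micrometres and a physical origin. Voxel `(i, j, k)` (1-based indices) has
its center at `origin + voxel_size * (c(i, j, k) - 1)`. The +z axis points
from the metaphyseal shaft toward the joint surface; `align_volume()`
enforces this, either with an explicit rigid transform or automatically by
rotating the principal axis of the mineralized mask onto +z. The automatic
mode replaces the manual alignment of an interactive workstation; it refuses
nearly isotropic masks (leading eigenvalue less than 1.1 times the second),
because the principal axis is then meaningless. Grayscale volumes are
resampled trilinearly, masks and labels with nearest-neighbor lookup so
labels are never blended.

Supported containers are multi-page TIFF, NRRD, MetaImage and raw+JSON, all
with voxel-size metadata; a TIFF stack carries none, so the voxel size must
be given explicitly — the package never assumes 1 µm silently.

## Median filtering

Tomographic shot noise is suppressed with a 3D median filter
(`median_filter_3d()`). The kernel parameter `k` selects a `(2k−1)³` window;
the default `k = 2` gives 3×3×3, the smallest odd window consistent with a
"small" kernel. This interpretation is a documented package choice: an
even-sized median window has no natural center, so a literal 2×2×2 reading
is not implementable as a centered filter. Borders use edge replication,
which keeps the window size odd everywhere; consequently binary volumes stay
binary and the filter's output range is always a subset of the input range.
On sparse binary noise (foreground density ≲ 0.25) repeated application
reaches a fixed point within a few sweeps; near density 0.5 the iteration
keeps evolving for many sweeps, which is a property of median dynamics at
critical density, not of this implementation.

## Segmentation and compartments

`region_grow(vol, seeds, c(lo, hi), connectivity)` selects exactly the
connected components of `{gray ∈ [lo, hi]}` that contain a seed. Default
connectivity is 26: bridges are thin, often oblique structures that
face-connectivity (6) would fragment. A seed whose own gray value lies
outside the interval is an error, not an empty result. Because the epiphysis
and metaphysis are disconnected whenever no bridge crosses the plate, the
pipeline seeds both compartments (one seed in the lowest, one in the highest
mineralized slice).

`label_compartments()` locates the growth-plate band as the z-interval of
minimal mineralized cross-sectional area between the two bone compartments:

* the per-slice area profile is smoothed with a 5-slice moving average;
* candidate slices are those whose smoothing window lies fully inside the
  mineralized z-range (edge windows are biased low by empty slices);
* the band seed is the smoothed argmin, with ties broken by the raw area —
  necessary when the gap is thinner than the smoothing window;
* the band is the contiguous run of slices whose raw area stays strictly
  below `min + 0.25 (max − min)` of the profile.

A monotone profile (no compartment on one side) or a missing interior
minimum is an error that asks for an explicit `gp_band`; a supplied band is
honored verbatim. Label codes are 0 background, 1 epiphysis, 2 metaphysis,
3 growth-plate cartilage and 4 bridge candidate (mineralized voxels inside
the band). The fifth code exists so that downstream consumers — bridge
detection and the FE material map — can distinguish mineralized tissue
inside the band without re-deriving it.

## Bridge detection, filtering, centers

A bridge is a connected component of mineralized voxels inside the band that
is adjacent, under the chosen connectivity, to both the epiphysis and the
metaphysis. This topological criterion operationalizes "crossing the entire
growth plate width" and replaces observer clicks; a click-list mode
(`seeds =`) restricts detection to chosen components when manual curation is
wanted. Ids are deterministic (sorted by bounding-box minimum z, y, x).

`filter_by_volume()` removes bridges smaller than 125 voxels — the
partial-volume cutoff — and retains a component of exactly 125. The
threshold is configurable but 125 is the default everywhere.

`bridge_centers()` reduces each bridge to one point. The default method
skeletonizes the component by topology-preserving sequential thinning
(simple-point tests: one 26-connected foreground component in the
26-neighborhood and one face-connected background component in the
18-neighborhood; endpoints preserved; voxels eroded in increasing
distance-to-background order, ties by linear index, so the result is
deterministic) and returns the skeleton voxel nearest the component
centroid, with lexicographic `(z, y, x)` tie-breaking. This center is
guaranteed to lie inside the component; the plain centroid of a bent bridge
is not, which is why `method = "centroid"` is offered only as a diagnostic.
A single-voxel component is its own center (logged).

## Projection and areal density

Bridge centers are projected along straight +z lines onto the joint surface,
the per-column height map of the topmost mineralized voxel over the
epiphyseal footprint. Heights at non-integer column positions are bilinear
in the four surrounding columns; if any of those columns lies off the
footprint the point is reported `missed` — misses are data, never silently
dropped, and never counted in densities.

The areal number density N_A is the count of projected centers per square
window (default 256 µm) in a grid of half-open tiles
`[x0+mw, x0+(m+1)w) × [y0+nw, y0+(n+1)w)`. Half-open intervals guarantee
each point is counted exactly once, so window counts always sum to the
number of projected points. The grid anchor defaults to the minimum (x, y)
of the point set and is recorded in the result; the choice of anchor is a
package decision (no anatomical registration is attempted), so density maps
from different grids should only be compared after fixing `grid_anchor`.
Tiled (non-overlapping) windows are assumed. `render_overlay()` writes a
deterministic PNG heat map and an ASCII PLY surface colored by the density
of the containing window.

## The phantom generator

`phantom_spec()`/`generate_phantom()` rasterize a known geometry — a
metaphyseal plate, a cartilage gap, an epiphyseal plate with optional
sinusoidal surface undulation along x, and cylindrical bridges (tilt up to
30°) spanning the gap — into a label volume (the exact ground truth) and a
grayscale volume with per-tissue means plus Gaussian noise. Defaults are
chosen as realistic CT contrast: background 20, cartilage 60, bone 200 gray
units with noise SD 5, i.e. a bone–cartilage separation of 28 SD. The spec
constructor enforces separations of at least 4 SD so segmentation stays
well-posed by construction. Overlapping bridges are rejected with the
offending pair named; generation is deterministic per seed.

`sweep_bridge_volumes()` instead places spanning components with *exact*
requested voxel counts by direct voxel placement: a full 1×1 column through
the gap plus extra voxels filling a compact box column-by-column in snake
order (face-connected by construction, components isolated by ≥3 empty
columns). This is the instrument for characterizing volume-threshold
filters. Note that a component of `v` voxels can only span a gap of `g ≥ v`
slices, so sweeps that must include very small volumes use a thin gap (the
1–300 sweep in the acceptance script uses a 1-voxel gap).

What the phantoms emulate: tissue contrast, additive Gaussian noise, thin
oblique bridges, surface undulation, disconnected compartments. What they do
not: beam hardening, ring artifacts, partial-volume blur at interfaces,
anatomically realistic bone shapes, spatially correlated noise. Passing the
recovery suite therefore demonstrates the correctness of the chain's
geometry and bookkeeping, not robustness to every scanner artifact; on real
scans, tolerance intervals and (where needed) the band hint remain the
user's responsibility.

Pipeline recovery on phantoms is exact by design: the recovery chain
segments the *unfiltered* volume (at default contrast the per-voxel
misclassification probability is ≈ 0), because median filtering erodes the
rims of thin cylinders and would break exact volume recovery. The filter's
value is established separately: at the maximal admissible noise
(SD = separation/4) segmentation after filtering still agrees with the
noiseless labels on ≥ 99.5 % of voxels.

## Finite-element model

Units are mm–MPa–N: voxel pitches in µm are converted to mm at meshing, so
moduli in MPa and loads in N combine without scale factors.

`mesh_from_labels()` optionally bins the label volume (majority vote per
block, ties toward the smaller label code) and splits every retained voxel
into 5 tetrahedra with the parity-alternating decomposition — corner tets of
volume h³/6 plus a central tet of h³/3, mirrored on odd-parity voxels so
faces conform across neighbors. The summed element volume equals the
retained voxel volume exactly. Materials: labels 1, 2 and 4 are bone, label
3 growth-plate cartilage; defaults are E = 17 000 MPa, ν = 0.3 and
E = 6 MPa, ν = 0.49. The mesh density is controlled by `bin_factor` and is
meant to be chosen with `mesh_sensitivity()`: given a strictly increasing
series of element counts with a scalar metric each, the asymptote is the
finest-mesh metric and the chosen mesh is the coarsest one that enters the
5 % band *and stays in it on every finer mesh*; the finest mesh itself
cannot demonstrate convergence (it defines the asymptote), so a series that
only reaches the band there is rejected with the convergence table attached.
Any scalar metric series is accepted — the procedure does not prescribe
which stress summary to monitor.

The static load case fixes the vertical displacement of all bottom-face
nodes, blocks rigid-body motion with three deterministic extremal pin nodes
(minimum-(x, y) node fixed in x, y; maximum-x node in x; maximum-y node in
y), and applies the total force (default 1 N, on the order of three times an
adult mouse's body weight) in −z, half to the medial and half to the lateral
side of the top surface. Within each side the default distributes force
equally per node; `split = "consistent"` uses tributary-area weights from
the boundary triangulation, which is the work-equivalent loading for a
uniform traction and the right choice for verification against closed-form
bar solutions; `regions = "all"` loads the whole top as one region for such
verification problems.

Assembly is standard constant-strain TET4 isotropic elasticity, solved with
a sparse symmetric factorization after eliminating prescribed DOFs.
Contracts, all tested: relative residual on the free equations ≤ 1e−8 (in
practice ~1e−12); reactions balance applied loads componentwise; the patch
test (linear displacement imposed on the boundary) reproduces the uniform
stress state to ~1e−15 relative for both tissue materials; a uniform column
matches F·L/(E·A) and a bone-on-cartilage stack matches the series-spring
closed form to machine precision under consistent loading. A missing
translational constraint is diagnosed by name; other singular systems
surface as factorization errors with a rigid-body-mode hint.

On a phantom with a single bridge, the bridge — a stiff strut through a soft
layer — carries the load: its peak von Mises stress exceeds the median
growth-plate stress by orders of magnitude (the test asserts a factor of 2
as a conservative bound). This reproduces the mechanism by which bridges act
as stress concentrators; it is a qualitative property check, not a
quantitative stress prediction for any particular bone.

## Problem sizes and determinism

The test suite builds all fixtures in code. Recovery runs 40 pipelines on
128³ phantoms (k = 0, 1, 5, 12 bridges × 10 seeded layouts); oracle
comparisons use 16³–32³ volumes; FE verification meshes range from 5 to
~10⁵ elements, and the stress-concentration phantom meshes ~60 000 elements.
These sizes were chosen so the full suite exercises every contract at
useful scale while remaining quick on a single CPU. Every stochastic step is
seeded; identical configurations produce byte-identical tabular outputs, and
the pipeline records all effective parameters plus the package version in
`provenance.json`.

## Known limitations

* The band locator assumes one growth plate in the field of view with bone
  on both sides; fragmentary or doubled plates need an explicit band.
* Density windows are tiled, not sliding, and the grid anchor is data-driven
  rather than anatomical.
* Projection is strictly along +z; no surface-normal option.
* The FE model is linear elastic and static: no poroelastic or viscoelastic
  cartilage, no contact, no growth simulation, and no stress measures beyond
  the von Mises summary.
* Meshing is voxel-based; it inherits the stair-step boundary of the
  segmentation rather than smoothing it.
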