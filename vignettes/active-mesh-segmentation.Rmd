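---
title: "Active-mesh segmentation of 3D cell aggregates: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-mesh segmentation of 3D cell aggregates: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(activemesh)
```

This vignette is the package's account of its science: the deformable-mesh
model and its assumptions, the parameters that matter and why they default
to what they do, what the synthetic phantoms do and do not emulate, and the
numerical choices made where the design was genuinely open. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## The model

A segmentation unit is a closed, genus-0, outward-wound triangle mesh in
physical coordinates (µm). Vertices move by explicit Euler steps

    x <- x + step_size * (F_img + F_intrinsic + F_steric)

until the maximum per-vertex displacement stays below a tolerance for ten
consecutive iterations ("steady state"), or an iteration cap is reached.

**Image forces.** Both energies sample the volume along the vertex normal
`n` at unit-pixel steps (one pixel = the smallest spacing component) by
trilinear interpolation, clamped at the volume border so the boundary
exerts no spurious pull.

- The *perpendicular gradient energy* is a negated squared
  directional-derivative estimate built from derivative-of-Gaussian taps
  `k_i = -i/(sqrt(2π) σ³) exp(-i²/2σ²)`. It is most negative where the
  intensity edge under the normal is sharpest, so its finite-difference
  force pulls vertices onto the boundaries of filled bright objects
  (nuclei imaged with a DNA stain). The printed form of the tap
  denominator is typographically ambiguous in its source; since both
  energies normalise by `Σ|k_i|`, any positive prefactor cancels and only
  the kernel shape matters — the tests pin the shape, not the prefactor.
- The *perpendicular intensity energy* is the negated Gaussian-weighted
  mean intensity along the normal; its gradient along `n` is the
  derivative of the smoothed profile. One sign subtlety is worth
  recording: correlating the antisymmetric taps with the profile gives
  *minus* that derivative, so the package implements the force as the
  convolution `Σ_i k_i I(x - i n)`, which makes a positive image weight
  climb toward bright sheets (membranes) and a negative weight descend —
  on a distance-transform volume, toward the transform's minima at object
  boundaries. This matches the described behaviour of both deformation
  modes and is asserted by sign tests on ramps and bright planes.

**Intrinsic forces.** `F = -α L(x) - β L²(x)` with `L` the uniform graph
Laplacian (`L(x)_v = x_v - mean of neighbours`). The first-order term acts
as surface tension: a free mesh shrinks monotonically, smoothing the
surface and — crucially — collapsing meshes that have nothing to wrap,
which is what turns non-convergence into a false-positive filter
(`filter_small()`, default floor: the volume of a 1.5 µm-radius ball). The
appendix-level discretisation used by the original interactive tool is not
reproduced here; the uniform Laplacian is the standard, documented
substitute, and the behaviour contract (shrinkage, smoothing, translation
invariance) is what the tests pin.

**Steric interactions.** During a deformation the neighbouring meshes are
fixed, so their union is voxelized once into a penetration-depth field
(erosion depth in voxels, converted to µm). Each vertex found inside a
neighbour is pushed back along its own reversed normal with a force
proportional to the sampled depth. The voxel resolution of this field (half
a voxel at the surface) is ample for the sub-1% overlap the membrane stage
needs, and sampling it trilinearly keeps the force smooth.

## Parameters, units and defaults

| parameter | meaning | default | unit |
|---|---|---|---|
| `sigma`, `w` | kernel width / half-width | 2, 5 (raw images); 1, 3 (distance transforms) | px |
| `w_img` | image-force weight | mode-specific | — |
| `alpha`, `beta` | tension / bending weights | see below | — |
| `step_size` | Euler step | 0.1 | — |
| `max_step_px` | per-iteration displacement cap | 0.5 | px |
| `tol` | convergence displacement | 0.01 | µm |
| `remesh_every` | remeshing cadence | 50 | iterations |
| `l_min`, `l_max` | remeshing edge band | 1, 3 | px |
| `theta` | seeding threshold on dt | 3 | — |
| `theta_floor` | watershed growth floor | 1 | — |
| `v_min` | shrinkage filter floor | 1.5 µm-radius ball | µm³ |

The balance between `alpha` and `w_img` is *condition-specific by
construction*: the image force on a distance transform scales with the dt
slope per pixel (≈ 1), while the uniform-Laplacian tension scales with the
squared mesh edge length times curvature — so the same `alpha` produces
different equilibria at different voxel sizes and object radii. The
packaged defaults (`nucleus_dt_params()`: `w_img = -2, alpha = 5`;
`membrane_dt_params()`: `w_img = -2, alpha = 1.5`; both `sigma = 1, w = 3`)
are set for the bundled phantom conditions — 0.35 µm voxels and 4 µm
nuclei. On other grids the weight should be rescaled the way the package's
own unit tests do (roughly `alpha ∝ 1/h²` in pixels for equal tension); the
narrower dt kernel (`sigma = 1, w = 3`) is used because the smoothed-dt
gradient extends one kernel reach beyond the true boundary and a wide
kernel would bias the equilibrium outward.

The seeding threshold of 3 (with a watershed floor of 1) is the working
value that separates nuclei whose interiors nearly touch; a threshold of 1
keeps everything strictly interior but merges close pairs — both behaviours
are pinned by tests on two-ball geometries.

## Label semantics

`make_labels()` produces the (mask, border, saturated distance transform)
triplet by iterative 6-connected erosion; the border is the depth-0 shell
and the transform saturates at 32. By default the erosion runs on the
*union* of all meshes — the printed label-generation procedure, and the
semantics under which touching nuclei merge below the seeding threshold.
The `per_instance = TRUE` variant erodes each instance against its own
boundary, so touching cells keep border voxels and dt zeros along their
shared interface. The pipeline's oracle membrane predictor uses the
per-instance form: the phantom's cells tile space exactly, so a union dt
would have no interface minima at all, whereas real membrane training
meshes are manually curated, do not tile space, and naturally leave the
interface minima that membrane meshes converge to. On disjoint instances
the two forms agree voxel for voxel.

The Dice-form losses are implemented exactly as printed,
`(|T·P| + 1)/(|T| + |P| + 1)` — a form that evaluates to ≈ 0.5 on a perfect
large match and 1 on empty sets. Whether the original training code
minimised this form or the conventional complement is not stated in the
text; the printed form is the default and the complement
(`1 - 2|T·P|/(|T| + |P| + 1)`) is available behind `form = "complement"`
(and is what the miniature trainable predictor uses, since the printed form
is not a useful descent target). The log-MSE loss takes the mean inside the
logarithm — the only reading that stays finite on typical batches — with an
epsilon of 1e-8 guarding the perfect match.

## Seeding, membranes and tracking

Seeding thresholds the dt at 3, labels components under 26-connectivity
(generous grouping of a single core; erosion stays 6-connected — a
deliberate asymmetry), filters by voxel-count bounds (default lower bound:
a 1 µm-radius ball), expands by marker watershed on the negated dt down to
the floor of 1, and raycasts an icosphere (2 subdivisions, 162 vertices;
refined later by remeshing) from each region's center of mass to its inner
surface. Ray marching steps at a quarter of the smallest spacing.
Watershed ties break toward the lower label; component labels follow array
scan order — the whole pipeline is deterministic given its inputs.

Membrane meshes start as copies of the nucleus meshes and deform on the
membrane dt with a negative weight and steric repulsion; two sweeps are run
so that meshes deformed early also feel the final shapes of meshes deformed
after them. This initialisation assumes nuclei sit reasonably central in
their cells — the regime of tightly packed epithelial aggregates, which the
phantom emulates. In loosely packed geometry (cells much larger than their
nuclei) the mesh starts on a dt *slope* and a descent-driven surface will
slide toward the nearest boundary instead of expanding; that failure mode
is real, documented here, and bounded in the phantom by its packing.

Tracking links frames greedily by bounding-box Jaccard index above a floor
of 0.1, ties toward lower identifiers. Divisions are recognised two ways:
a vanished track whose last box overlaps two or more newborn boxes (the
plain rule), and a re-classification for the common case where greedy
linking swallows one daughter — a track whose matched box shrinks below
0.75× its previous volume while a newborn box also lies ≥ 60% inside the
previous box ends as a parent and both meshes start child tracks. Detection
scoring maps predictions and truths to each other by highest bbox overlap;
only mutually-singly-mapped pairs are true positives, multiply-mapping
predictions are false positives, and every other truth (unmapped, shared,
or non-mutual) counts as a false negative. Zero-overlap mappings count as
unmapped, so stray predictions far from any truth are not tallied as false
positives by the box rule alone.

One property worth stating precisely: the number of seed regions is *not*
monotone in the threshold — that is the point of thresholding at 3 (one
merged region at θ = 1 splits into two at θ = 3). What does hold, and what
the suite tests, is the refinement hierarchy: every region at a higher
threshold is contained in exactly one region at any lower threshold.

## The synthetic phantoms

`generate_frame()` emulates a small organoid at half resolution: a 128³
grid of 0.35 µm voxels holding ~10 tightly packed cells. Nuclei are
randomly oriented ellipsoids (axis ratio ≤ 1.5, mean semi-axis 4 µm ≈ an
8 µm diameter) so meshes must genuinely deform; cells are the Voronoi
partition of the aggregate ball around the nucleus centers; membranes are
1-voxel bright shells on cell-cell and cell-exterior boundaries; both
channels get a Gaussian PSF and mild Poisson + Gaussian noise. Nucleus
centers are placed by best-candidate sampling with a minimum separation of
2.05 nucleus radii — about the densest packing the geometry admits, and the
regime in which nuclei nearly fill their cells (cell radius ≈ 1.4× nucleus
radius), as in the epithelial aggregates this pipeline targets. Scheduled
divisions replace a cell with two 0.62-scale daughters along an axis chosen
to maximise clearance from neighbours, so daughters are separable at the
seeding threshold from their first frame.

What the phantoms do *not* emulate: realistic light-sheet or spinning-disc
optics (the PSF is isotropic Gaussian), photobleaching, dye-accumulation
artifacts, nuclear-envelope breakdown during mitosis, irregular cell
shapes (membrane appendages), or imperfect predictor output beyond additive
Gaussian noise on the dt. Passing tests therefore demonstrate the
machinery's correctness and the method's behaviour under controlled
conditions, not segmentation accuracy on real microscopy data — a network
predictor trained on real labels sits between the raw data and this
pipeline exactly so that the downstream stages see a cleaned-up, nearly
phantom-like field.

The miniature trainable predictor (`train_tiny_unet()`) is a compact
single-stage 3D convolutional model with three heads (sigmoid mask and
border, clipped-linear dt), trained full-batch with hand-derived gradients
and backtracking step halving, so its recorded loss history is
non-increasing and bit-reproducible given the seed. It is a testing vehicle
for the predictor contract, not a high-capacity network; the oracle
predictor (`oracle_predict()`, exact labels with optional seeded dt noise)
is the canonical path for exercising the downstream stages.

## Numerical choices and degenerate inputs

- Coordinates: arrays are `(z, y, x)` (TIFF page order); voxel `(k, j, i)`
  centers sit at `origin + ((k-1) sz, (j-1) sy, (i-1) sx)`; mesh vertices
  are `(x, y, z)` µm.
- Point-in-polyhedron uses ray parity along +x with a deterministic
  sub-voxel perturbation of the ray against exact edge/vertex hits.
- Remeshing is batched isotropic remeshing: long-edge bisection (safe to
  apply to every long edge of a sweep, since splits move no vertices),
  link-condition-guarded short-edge collapse, and gentle tangential
  Laplacian relaxation. The upper edge bound is enforced; the lower bound
  is best-effort because a collapse is refused whenever it would break
  manifoldness. Infeasible bands fail fast against a vertex budget.
- Deformation caps per-vertex displacement at 0.5 px/iteration for
  stability; convergence demands the displacement stay under 0.01 µm for
  ten consecutive iterations, and the window resets when remeshing changes
  the topology.
- Degenerate inputs error loudly: open meshes cannot be voxelized, empty
  regions cannot seed, a region whose center of mass falls outside itself
  is invalid geometry, zero-area faces contribute nothing to vertex
  normals and a vertex whose averaged normal vanishes is an error.
- Problem sizes used by the suite: phantoms of 4–10 cells on 64³–128³
  grids, 50 random blob volumes up to 64³ for the erosion oracle, and a
  6-frame 96³ time-lapse for tracking; chosen so the full suite and the
  acceptance script each complete in minutes on one core while still
  exercising every stage at realistic geometry.

## Known limitations

- The α/w_img balance is resolution- and size-dependent (see above);
  defaults target the bundled conditions and need rescaling on other
  grids.
- Descent-driven membrane deformation requires the initialisation (the
  nucleus mesh) to lie within the basin of its cell's dt interior; very
  eccentric nuclei in oversized cells can slide to the nearest boundary
  instead.
- Genus-0 surfaces only; no topology changes (splitting/merging) during
  deformation.
- Tracking is greedy frame-to-frame, not globally optimal assignment;
  identity preservation is tested for slow motion relative to cell size.
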