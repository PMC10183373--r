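# activemesh

Segmentation of cell nuclei and cell membranes in 3D fluorescence volumes of
small cell aggregates (tens of cells, e.g. organoids or embryonic stem-cell
colonies), using **active meshes**: closed triangulated surfaces that are
iteratively displaced by image-derived and intrinsic forces until they wrap
the structure of interest. The package provides the full surrounding
pipeline — training-label generation, distance-transform-driven instance
seeding, membrane segmentation, bounding-box tracking, instance-level
evaluation — together with a synthetic two-channel phantom generator with
mesh ground truth, so every stage can be exercised and scored without any
external data.

## The method

A segmentation mesh is a closed genus-0 triangle mesh in physical
coordinates (µm). Each vertex `x` with outward unit normal `n` feels an
image force plus intrinsic regularisation, and is updated by explicit Euler
steps until steady state.

Two image energies couple the mesh to the voxel data, both built from a
derivative-of-Gaussian tap set `k_i = -i/(sqrt(2π) σ³) exp(-i²/2σ²)`,
`i ∈ [-w, w]` (defaults σ = 2 px, w = 5 px):

- **Perpendicular gradient energy** (filled bright objects, e.g. nuclei):
  `E(x) = -[Σ_i k_i I(x + i n) / Σ_i |k_i|]²`, a negated squared
  directional-derivative estimate; the force is the central difference
  `F = -(w_img/2) [E(x+n) - E(x-n)] n`, attracting vertices to intensity
  edges.
- **Perpendicular intensity energy** (bright sheets, e.g. membranes, or
  distance transforms): `E(x) = -Σ_u G_σ(u) I(x + u n) / Σ_u G_σ(u)`, the
  negated smoothed mean along the normal; the force is the derivative of
  the Gaussian-smoothed profile along `n`, scaled by `w_img`. A positive
  weight climbs toward bright structures, a negative weight descends — on a
  distance transform this drives vertices to the transform's minima, i.e.
  object boundaries.

Intrinsic forces `F = -α L(x) - β L²(x)` (uniform graph Laplacian `L`)
penalise surface area and bending; with `α > 0` a free mesh shrinks, which
both stabilises the fit and filters false-positive seeds (a mesh with
nothing to wrap collapses and is removed by a volume floor).

Around this core:

- `make_labels()` converts mesh sets into the three training labels used by
  voxel predictors: binary mask, border, and an erosion-depth **distance
  transform** saturated at 32 (6-connected erosion; the border is depth 0).
  `dice_loss()`, `log_mse_loss()` and `total_loss()` implement the
  composite training loss.
- `threshold_regions()` / `grow_regions()` / `seed_meshes()` turn a
  (predicted) distance transform into instance seeds: connected components
  of `{dt ≥ 3}`, marker watershed down to `{dt ≥ 1}`, then icosahedral
  raycast meshes per region. `segment_nuclei()` chains these with the
  deformation; `segment_membranes()` re-deforms nucleus meshes onto the
  membrane distance transform with steric repulsion between neighbours.
- `best_ji_map()` scores instances by best Jaccard index
  `JI_i = max_j |T_i ∩ P_j| / |T_i ∪ P_j]` and centroid offset ΔCM;
  `detection_match()` tallies TP/FP/FN by bidirectional bounding-box
  mapping; `track_bboxes()` links instances over time and flags divisions.
- `generate_frame()` / `generate_timelapse()` build two-channel phantoms
  (ellipsoidal nuclei in a Voronoi-partitioned aggregate, membrane shells,
  PSF blur, Poisson + Gaussian noise, drift, scheduled divisions) with
  ground-truth meshes, labels and tracks.

## Worked example

Segment a noiseless ten-cell phantom end to end and score it against its
own ground truth:

```r
library(activemesh)

fr  <- generate_frame(phantom_spec(n_cells = 10, psf_sigma_px = 0,
                                   noise_gaussian_sd = 0,
                                   noise_poisson_scale = 0, seed = 1))
out <- run_pipeline(fr)
m   <- out$metrics[[1]]

unlist(m$detection)
#> TP FP FN
#> 10  0  0
round(m$ji$records$best_ji, 3)
#>  [1] 0.949 0.926 0.924 0.938 0.958 0.936 0.945 0.946 0.967 0.980
round(m$ji_membrane$records$best_ji, 3)
#>  [1] 0.920 0.868 0.924 0.873 0.880 0.887 0.946 0.901 0.881 0.879
```

All ten nuclei are detected (no false positives or negatives); the
volumetric best Jaccard index of every recovered nucleus mesh is above
0.92, and of every membrane mesh above 0.86, against the generating
geometry. `out$tracks` holds the time-linked identities when several
frames are supplied.

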