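---
title: "Quantitative 2.5D morphometrics of the shoot apical meristem: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative 2.5D morphometrics of the shoot apical meristem: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The measurement problem

At floral transition the shoot apical meristem (SAM) of *Arabidopsis*
enlarges and domes: the meristematic area grows several-fold, the number of
epidermal (L1) cells increases, and the cells themselves transiently
enlarge. Quantifying this requires delimiting the meristem proper on a
curved surface, segmenting its epidermal cells, and measuring per-cell
areas — all from confocal stacks of wall-stained apices imaged top-down.

`meristemorph` implements this pipeline as a reusable, tested R package:

1. **Surface extraction** — the epidermal surface as a heightmap mesh.
2. **Cell segmentation** — seeded watershed of the projected wall stain on
   the mesh vertex graph.
3. **Curvature** — discrete Gaussian curvature K at a fixed 10 µm
   neighborhood.
4. **Delimitation** — the meristem as the connected cell set around the
   summit bounded by saddle (K < 0) cells.
5. **Zonation** — central zone (CZ, cells 0–2 graph steps from the summit
   cell) and peripheral ring (PZ, steps 3–5).
6. **Quantification** — meristem area, cell number, per-cell and per-zone
   cell areas; reporter-signal projection in a 2–10 µm depth band;
   one-way ANOVA + Tukey HSD + compact letter display across groups.

Because real apices of this kind are not publicly deposited, the package
ships a synthetic apex generator whose scenes carry complete ground truth,
so every stage is testable end to end and the headline doming effect sizes
are recoverable as known quantities.

# The 2.5D geometry

All analysis happens on a *heightmap* surface: one height per lateral
position, triangulated on the pixel grid in physical µm. This matches
top-down imaging of the L1 and deliberately excludes overhangs (a mature
flower pressed under the meristem flank would violate the heightmap
assumption; such apices are out of scope). Axis order of stacks is
(z, y, x); slice 1 is the top of the stack; z decreases by the slice step
(0.4 µm by default, the acquisition step the pipeline is designed around);
lateral pixels default to 0.5 µm.

Surface extraction takes the topmost voxel above a threshold per column
(heights therefore quantized at the z step), applies a 3×3 median filter,
and then Gaussian-smooths the height map (`smooth_sigma`, default 2 µm).
The smoothing scale sits an order of magnitude below the 10 µm curvature
neighborhood, so it perturbs the curvature field only at second order,
while suppressing the 0.4 µm height quantization that otherwise dominates
K on nearly flat (vegetative) apices. Set `smooth_sigma = 0` to disable.

# Gaussian curvature at a fixed physical radius

Per vertex, all vertices within a **geodesic** radius (Dijkstra over mesh
edges; default 10 µm) are collected and a local polynomial height field is
fitted in the tangent frame of the vertex normal. K is the determinant of
the shape operator of the fitted surface at the vertex:
\(K = (4ac - b^2) / (1 + d^2 + e^2)^2\) for the fitted
\(h(u,v) = a u^2 + b uv + c v^2 + d u + e v + \dots\).

Two numerical choices matter:

* **Fit degree.** A bare quadric is biased at this neighborhood size: on a
  sphere of radius 25 µm a 10 µm patch has appreciable quartic height
  terms, which alias into the quadratic coefficients (~7% K bias). The
  estimator therefore fits a degree-4 jet whenever the ball holds at least
  30 neighbors and falls back to a quadric below that; coordinates are
  scaled by 1/radius inside the fit for conditioning. The test suite
  checks K on spheres, planes and saddles against closed forms.
* **Undefined is explicit.** Vertices with fewer than 6 in-radius
  neighbors, or a rank-deficient fit, are flagged `NA`, never silently
  zeroed. Downstream per-cell averages use defined vertices only.

The angle-defect (Gauss–Bonnet) estimator is implemented independently
(`angle_defect_curvature`) and retained purely as a cross-check of
curvature sign in the tests; it is resolution-dependent and not used for
the fixed-radius maps.

Invariances verified by the suite: rigid motions leave K unchanged to
floating-point accuracy; scaling the mesh *and* the neighborhood radius by
s scales K by 1/s² (the radius is a physical length, so a fixed 10 µm
radius on a rescaled mesh is a different estimator by design).

# Watershed segmentation on the vertex graph

The wall stain is projected onto mesh vertices as the mean of trilinear
samples along the inward normal over a 0–4 µm depth band (the outer cell
layer). The watershed floods this field over the *mesh vertex graph* — not
a flat image — so basin boundaries follow wall ridges on the curved
surface and cell areas are surface areas. Seeds are either supplied
(e.g. one per known cell) or computed as regional minima after h-minima
suppression with h = 10% of the field's dynamic range, via morphological
reconstruction by erosion on the same graph. Basins below `min_cell_area`
(default 4 µm², well under any epidermal cell) are merged into the
neighbor with the longest shared boundary. The flood is a priority queue
with deterministic tie-breaking, so segmentation is reproducible
bit-for-bit.

# Delimitation, zonation, primordia

**Meristem region.** Per-cell curvature is the area-weighted mean of
defined vertex K within the cell. Starting from the central cell, the
region grows across the cell-adjacency graph through cells with K ≥ 0;
the first K < 0 cells encountered form the boundary. Boundary (saddle)
cells are *excluded* from the region by default — the conservative
reading of "cell area in the meristem region" — and `include_boundary`
toggles the convention. A central cell with K < 0 is an error (no
meristem found), not an empty result.

**Central cell.** The cell containing the vertex with maximal coordinate
along the apex axis (+z), ties broken by lowest vertex index; a vertex
shared by several cells belongs to the cell owning most of its incident
triangles. Height maximum rather than curvature maximum was chosen as the
summit criterion; a curvature peak is easily obtained from the per-cell K
map if wanted.

**Zonation.** Ring r of a cell is its breadth-first distance from the
central cell restricted to region cells; CZ = rings 0–2, PZ ring =
rings 3–5. These are topological (cell-count) distances, matching how
central and peripheral cell populations are compared.

**Primordia.** Connected components of K > 0 cells outside the region
become existing primordia P_n if they exceed a minimal area (25 µm²
default) *and* a minimal mean curvature (`min_mean_K`, default
1e-4 µm⁻²). The curvature floor matters: where two primordium flanks
interfere, small flank patches can cross K = 0 with near-zero magnitude;
genuine bumps sit two orders of magnitude above the floor (K of order
1/radius²). Age rank 1 is the youngest (smallest) bump. Incipient
positions i_n are extrapolated from the youngest P by successive
divergence-angle steps (137.5°, the golden angle, by default — standard
spiral phyllotaxis; the divergence is a parameter throughout), placed
radially on the region boundary.

**Distances on the surface.** `curvilinear_distance` computes arc length
of a shortest on-surface polyline (optionally through a `via` point such
as the summit, for the distance between opposite primordia). It runs
Dijkstra on a Steiner-augmented graph (two extra nodes per edge plus face
centroids, completely connected within each face) and then tightens the
polyline by sliding interior nodes along their supporting edges/faces.
This is a reproducible surrogate for interactive curve tracing; the
sphere great-circle test bounds its error well below 1%.

# Reporter-signal projection

Fluorescent reporter stacks are projected per vertex as the mean (or, by
flag, maximum) of trilinear samples along the inward normal across a
2–10 µm depth band below the surface, then aggregated per cell as the
area-weighted mean over the cell's vertices. Sampling steps at half the
smallest voxel dimension. Vertices whose ray exits the stack are flagged
and excluded; a cell with no defined vertex is `NA`, never zero. No
per-apex intensity normalization is applied by default. Heat maps
(cell area, signal) are rendered top-down orthographically to PNG with a
monotone colormap and a recorded color range; rendering is
byte-deterministic.

# Group statistics

Groups are genotype × condition combinations, compared by one-way ANOVA
followed by Tukey HSD (studentized-range adjusted p, Tukey–Kramer for
unbalanced designs) via `stats::aov`/`stats::TukeyHSD`, with a compact
letter display computed by insert-and-absorb: groups share a letter iff
their adjusted p is at or above alpha (0.05 default). Zero within-group
variance is reported with an explicit `degenerate` flag (p = 0 for
separated means, 1 for identical ones). The test suite checks the
adjusted p-values against an independent numerical integration of the
studentized-range CDF, the empirical type-I error under the null, the
familywise error over four equal groups, and the letter contract on
random p-matrices. Fold-change tables report ratios of group means to a
baseline condition, with per-apex values retained.

# The synthetic apex generator

`generate_apex_scene(apex_preset(name), seed)` builds a complete scene:
mesh, ground-truth segmentation, region, primordia, incipient positions,
and a rendered wall-stain stack. Identical (preset, seed) pairs are
bit-identical, and generation leaves the caller's RNG state untouched.

**Dome.** The apex is a Gaussian dome \(z = h\,e^{-r^2/2s^2}\). This
profile was chosen because its Gaussian curvature changes sign *exactly*
at r = s regardless of height — the saddle annulus that defines the
meristem boundary is analytic, and the cap width s is solved numerically
so that the surface area inside r = s equals the preset's nominal
meristem area. Primordia are Gaussian bumps at successive golden-angle
positions, ages (and sizes) increasing away from the youngest, placed at
three bump-widths beyond the cap edge so their tails perturb the K = 0
circle negligibly; a bump that would overlap the summit dome or rival its
height is an error, not a silent clip.

**Tessellation.** Epidermal cells are laid out as annular rings of
near-square sector cells in the dome's equal-area radial coordinate, each
cell's angular width proportional to its prescribed area. Cell areas are
therefore *exact* by construction (up to pixelation), the region holds
exactly `n_cells` cells, and the central cell is the innermost disk cell.
A centroidal-Voronoi tessellation was implemented first and abandoned:
Lloyd relaxation equalizes areas and destroys prescribed size
distributions, and a capacity-controlled power diagram converged too
slowly and noisily to guarantee the calibration (per-cell residuals of
5–20% from slow collective modes). The ring construction trades some
visual realism of cell shapes for exact, deterministic control of the
quantity that matters here — the per-cell area distribution.

**Calibration.** The vegetative/domed preset pair encodes the doming
effect sizes as ground truth: meristem area ×4.0, region cell number
×3.5, median cell area ×1.8. Note these three cannot hold simultaneously
with symmetric cell-area distributions (area = cells × mean area forces a
mean-area ratio of 4.0/3.5 ≈ 1.14): they jointly require the vegetative
distribution to be right-skewed, with its median well below its mean.
The generator realizes this with three radial size blocks — small cells
centrally, median-sized cells in a middle annulus (40% of cells, tightly
scattered: it anchors the calibration), large cells peripherally — while
the domed preset is near-uniform. Smaller central cells are also the
biologically expected pattern. `cell_area_cv` (default 0.25) scatters
per-cell target areas multiplicatively while preserving block totals.

**Stacks.** The wall stack renders anticlinal walls as ridges of lateral
half-width 0.35 µm through a 5 µm L1 depth, plus a bright outer
(periclinal) coat in the top 0.8 µm; because real anticlinal walls run
perpendicular to the surface, the wall sheet at depth d is displaced
laterally along the height gradient and band membership uses the
along-normal depth — without this tilt correction, watershed rays on the
domed flanks cross neighboring wall sheets and oversegment. Reporter
stacks confine the pattern (`pz_patches` at the incipient positions,
`abaxial_primordia` on the outward side of bumps, `uniform`, `none`) to a
configurable depth band with additive Gaussian noise (`noise_sd`, default
2 intensity units against a wall amplitude of 100). The stack is padded
12 µm below the tissue base so depth bands never leave the volume.

**What the generator does and does not emulate.** It reproduces the
geometry that drives the measurements (dome, saddle, bumps, cell size
distributions, wall ridges, depth-banded reporters) with additive
Gaussian noise only. It has no confocal point-spread function, no
attenuation with depth, no wall-stain heterogeneity, no cell-shape
anisotropy, and static snapshots only — no growth dynamics. Passing
recovery tests on these scenes therefore demonstrates correctness of the
geometry and the pipeline logic, not robustness to every real-world
imaging artifact; on real stacks the extraction threshold and smoothing
are the parameters to revisit first. The mutant-like presets
(`ft_tsf_like`: lateral cap expansion without doming; `narrow_meristem`:
reduced cap width at unchanged cell size) are qualitative emulations, not
fits.

# Problem sizes and defaults

The calibrated presets produce meshes of roughly 10^5 vertices
(vegetative ~100k, domed ~200k at 0.5 µm pixels); one full
stack-to-record analysis takes tens of seconds on a single core, and the
six-apex doming comparison (two stages × three seeds, the *n* = 3 per
group design of the reporting workflow) runs in a few minutes. Unit tests
use miniature presets (~1000 µm² caps) for speed; the acceptance checks
use the full calibrated presets.

Key defaults, all exposed as arguments: curvature radius 10 µm;
z step 0.4 µm; xy pixel 0.5 µm; wall band 0–4 µm; signal band 2–10 µm;
CZ rings 0–2, PZ rings 3–5; watershed h-fraction 0.1; `min_cell_area`
4 µm²; extraction threshold 25% of stack maximum; height smoothing 2 µm;
divergence 137.5°; alpha 0.05.

# Known limitations

* Heightmap (2.5D) only: overhanging tissue is invisible by construction.
* Region erosion of a few percent is expected where boundary cells
  straddle the K = 0 circle, because saddle cells are excluded; the
  `include_boundary` flag flips the convention.
* The curvature estimator needs the neighborhood radius to exceed twice
  the median edge length, and is noise-limited on nearly flat apices at
  coarse z steps — hence the default height smoothing.
* No manual segmentation correction; errors on real data would need
  seeds or parameter changes instead.
* Letter displays use one-way ANOVA on combined genotype × condition
  groups; no two-way decomposition.
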