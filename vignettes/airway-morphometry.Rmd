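---
title: "Position-dependent airway morphometry: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position-dependent airway morphometry: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwaymorph)
```

## The measurement problem

Whether tracheal intubation will be difficult depends strongly on how the
air-filled space of the upper airway — the "airway filling", the region from
the oral cavity through the pharynx to the larynx — changes shape when the
head moves from the supine position to maximum extension (the "sniffing"
position).  In the supine position the oral, pharyngeal and laryngeal axes
cross at steep angles and the air path is bent; under maximum extension the
three axes nearly align and the path from the incisors to the glottis is
almost straight.  `airwaymorph` quantifies that change from 3D surface
models of the airway filling: the enclosed volume, the orthographic
silhouettes of the model on the three anatomical planes, and a small set of
quadrilateral shape descriptors per silhouette, compared within subjects
(supine versus extension) and between groups (normal versus difficult
airway).

All geometry is in millimetres under one fixed anatomical frame:
X = right to left, Y = posterior to anterior, Z = inferior to superior.
No axis convention is universal in this setting, so the package fixes one
globally and defines every plane and descriptor against it.

## Volume

The primary measure is the enclosed volume of the airway-filling surface.
For a watertight, consistently wound triangle mesh the divergence theorem
gives the volume exactly as the sum of signed tetrahedra spanned by the
origin and each face,

$$V = \Bigl|\tfrac{1}{6}\sum_{f} \det(v_{f,1}, v_{f,2}, v_{f,3})\Bigr|,$$

which is invariant to rigid motion and to the global winding direction.
Meshes are checked for watertightness (every undirected edge shared by
exactly two faces); a non-watertight surface falls back to voxel counting at
0.25 mm and the result is flagged.  The voxel oracle — occupancy of voxel
centers decided by vertical-ray crossing parity — is also exposed directly
(`voxelize()`, `voxelVolume()`) and serves as the independent cross-check of
the surface integral: the two agree within 2% on every phantom in the
validation grid, and the discrepancy shrinks with the voxel size.

Voxel masks (e.g. from a segmentation) enter through `maskToSurface()`,
which extracts the 0.5 iso-surface of the binary occupancy field by marching
tetrahedra on the Kuhn six-tetrahedron decomposition of each grid cube.  The
mask is padded by one empty layer first.  Because the iso-surface of a
piecewise-linear field at a regular value is a closed manifold, the output
is watertight for any non-empty mask; no smoothing is applied beyond the
iso-surfacing itself.

## Silhouettes on the anatomical planes

Each projection drops one world axis: the coronal plane drops Y, the
sagittal plane drops X, the horizontal (axial) plane drops Z.  The in-plane
axes are always ordered (u = transverse, v = longitudinal):
coronal (X, Z), sagittal (Y, Z), horizontal (X, Y).  The projection plane is
divided into square cells of 1 mm² by default, and a cell is occupied iff
its center lies inside any projected triangle.  Three numerical choices
matter here:

* **Binary center sampling, not partial coverage.**  The descriptor set
  counts whole cells, so boundary cells are in or out, never fractional.
  The resulting area error for a disc of radius ≥ 8 mm is below 2% at 1 mm
  cells and vanishes as the cell size shrinks.
* **Closed predicate.**  Centers exactly on a projected edge count as
  inside (tolerance 1e-9), so axis-aligned geometry does not drop its
  boundary cells; a 10 mm cube yields exactly a 10 × 10 block.
* **Deterministic anchoring.**  The grid starts at
  `floor(min coordinate / cellSize) − 1` cells, guaranteeing one empty
  margin cell on every side and making the raster invariant under
  translations by whole multiples of the cell size.

## The quadrilateral descriptor set

Per silhouette the package reports the projected area S (occupied cells ×
cell area), the transverse and longitudinal radial lengths L_T and L_L
(occupied extents along u and v, including the cell width), and two corner
angles of the key-point quadrilateral.  The four key points mark where the
silhouette touches its bounding box: left and right at the transverse
extremes, inferior and superior at the longitudinal extremes.  Where several
extreme cells tie, the point sits at the midpoint of the first contiguous
run of tied cells.

The key points are placed on the bounding box itself — the outer face of
the extreme cells — rather than at extreme-cell centers.  This is a
deliberate design choice: it makes the quadrilateral's diagonals equal the
radial lengths L_T and L_L exactly, so the corner angles follow the rhombus
geometry of the extents (a 40 × 20 mm rectangle gives a lower corner angle
of 2·arctan(40/20) = 126.87° and a left corner angle of 53.13°; a disc
gives 90°).  Center placement would bias every extent by one cell and shift
the rectangle's lower angle by more than 3°, an error that does not vanish
with finer rasters relative to the cell size.  All coordinates remain on
the half-cell lattice.

Angles are interior angles of the polygon traversed superior → right →
inferior → left: the "lower" angle at the inferior vertex, the "left" angle
at the left vertex, in degrees in (0, 180).  Since the key points lie on
four sides of the bounding box in rotational order the quadrilateral is
convex and its four interior angles sum to 360°, which the test suite
asserts on randomly generated shapes.  A silhouette whose occupied cells
lie in a single row or column is flagged degenerate: its quadrilateral
collapses to a sliver and the angles, while defined, are not meaningful.

`measureSubject()` assembles volume plus the five descriptors on all three
planes into a `MorphRecord`; records serialize to plain CSV with plane-coded
column names (`S_sag`, `L_T_cor`, `alpha_lower_hor`, ...), which together
with the `position` column carry the conventional position-subscripted
symbols (S_SS/S_ES, L_STS/L_ETS, and so on).

## Cohort statistics

Paired position changes are `extension − supine` differences per descriptor
with percentage rates `100 · difference / extension value`.  The extension
denominator is the default because it reproduces the published group-level
volume-rate arithmetic (a 6,324 → 9,187 mm³ group mean change is reported
as ~31%, which is the difference over the extension value); the supine
denominator is available as an option.  A zero denominator gives an `NA`
rate, not an error.

Between-group tests are classical two-tailed pooled-variance Student
t-tests; the era and software of the clinical workflow this emulates imply
the classical test, and Welch's variant is selectable.  Zero-variance edge
cases are resolved explicitly (t = 0, p = 1 when the groups coincide; an
infinite-t marker with p = 0 otherwise).  The pooled test is validated
against a 20,000-permutation oracle on small samples.  No multiple-testing
correction is applied by default, matching the emulated analysis.

Power for the two-sample two-tailed test is computed from the noncentral t
distribution with df = 2n − 2 and noncentrality d·√(n/2) — not from a
normal approximation — and includes both rejection tails.  At α = 0.05 and
n = 20 per group this gives 0.095, 0.338 and 0.693 for d = 0.2, 0.5 and
0.8, the conventional reference values at two-decimal precision.

## The phantom generator

No patient imaging ships with the package, so validation rests on a
parametric phantom: a tube of radius r swept along a circular arc of length
s in the sagittal (Y–Z) plane, subtending a bend angle θ, with capped ends.
The supine phantom is strongly bent (default θ = 90°, s = 80 mm), the
extension phantom nearly straight and longer (default θ = 15°,
s = 100 mm), emulating the straightening and lengthening of the air path
under head extension.  The bend lives in the sagittal plane because head
flexion–extension is a sagittal rotation, so the position change expresses
mostly in sagittal-plane descriptors — straightening increases the sagittal
projected area and transverse radial length in every matched pair, the
qualitative signature the pipeline is expected to detect.

The generator's key property is an exact volume oracle: by the Pappus
centroid theorem a circular cross-section centered on the arc sweeps
V = π r² s whenever the arc radius R = s/θ exceeds the tube radius (specs
violating that are rejected as self-intersecting).  A mid-path narrowing
profile r(t) is available to caricature pharyngeal narrowing; its volume is
then the quadrature of π r(t)² s dt, flagged as numeric.

`simulateCohort()` draws per-subject target volumes from group × position
normal distributions — defaults are the published cohort means and SDs
(normal group 6,323.83 ± 156.06 mm³ supine and 9,186.58 ± 512.61 mm³
extended; difficult group 5,336.22 ± 316.13 and 6,735.46 ± 794.63) — and
solves r = √(V/(π s)) so the analytic volume equals the draw.  The supine
and extension draws of a subject share one standard-normal subject effect,
which with the default targets makes extension exceed supine for every
subject; draws below half the target mean or inverted pairs are redrawn and
counted.  The seed is mandatory and echoed in the manifest, making every
cohort reproducible byte for byte.

What the phantom deliberately does not model: real anatomy (it is a single
stylized tube, not an oral/pharyngeal/laryngeal triple), imaging or
segmentation noise, tissue deformation, and non-circular cross-sections
beyond the radius profile.  Passing the validation suite therefore shows
that the measurement operators are correct on known geometry and that the
statistical pipeline recovers a known group structure — not that the
descriptors are clinically discriminative on real patients.

## Problem sizes and numerical tolerances used in validation

The validation suites run on: a 3 × 3 × 3 phantom grid
(r ∈ {3, 5, 8} mm, s ∈ {60, 80, 100} mm, θ ∈ {0°, 45°, 90°}) for the
volume-oracle (2%) and Pappus-closure (1%) checks at the default mesh
resolution of 64 sweep sections × 64 ring vertices (cross-section area
deficit of the inscribed 64-gon ≈ 0.16%); spheres of radius 8–10 mm for
raster and iso-surface convergence; and 200 seeded cohort replicates at
n = 20 per group for the end-to-end recovery of the between-group supine
volume difference.  The replicate phantoms use a coarser 16 × 16 mesh —
the ~1% uniform volume deficit at that resolution cancels in group
comparisons and per-subject orderings — while single-cohort descriptor
summaries use the default resolution.  Derived seeds stay below 2³¹.

Other fixed numerical choices: vertex merge tolerance 1e-6 mm on load;
point-in-triangle tolerance 1e-9 (closed predicate); voxel-oracle spacing
0.25 mm; iso-level 0.5; silhouette cell size 1 mm.  Known limitations:
PLY reading is ASCII-only; masks with strongly oblique header transforms
fall back to a zero origin (spacing is always honoured); and the
ray-parity voxelizer assumes a closed surface, so its non-watertight
fallback is only an estimate whose quality degrades with the size of the
surface defect.
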